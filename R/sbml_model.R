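#' Build a spatial SBML model from a labeled geometry
#'
#' Assembles the SBML-level container: cartesian coordinate components with
#' bounds `[0, extent * spacing]` per axis, one domainType and one
#' compartment per volume and membrane type, one domain record per labeled
#' region (interior points in physical, voxel-centre coordinates), the
#' adjacentDomains pairs, and a sampled-field geometry holding one
#' sampledVolume per *volume* domainType (membranes carry no sampled value)
#' plus the full voxel array.
#'
#' Compartment SIds equal the domainType name (`"Cyt"`); the corresponding
#' domainType SId is `"<name>_domainType"` since SBML identifiers share one
#' namespace. Volume compartment sizes are `voxel_count * dx * dy * dz`.
#'
#' @param geom a [merge_masks()] `LabeledGeometry`.
#' @param domains matching [label_domains()] `DomainSet`.
#' @param graph matching [create_membranes()] `AdjacencyGraph`.
#' @param id SBML model id.
#' @return An object of class `SpatialModel`.
#' @examples
#' fx <- nested_spheres(c(16, 16, 16), radii = c(6, 3))
#' geom <- merge_masks(fx)
#' doms <- label_domains(geom)
#' graph <- create_membranes(detect_adjacency(geom, doms), geom$depth_order)
#' m <- build_model(geom, doms, graph)
#' m
#' @export
build_model <- function(geom, domains, graph, id = "spatial_model") {
  if (!inherits(geom, "LabeledGeometry")) stop_input("'geom' must be a LabeledGeometry")
  if (!inherits(domains, "DomainSet")) stop_input("'domains' must be a DomainSet")
  if (!inherits(graph, "AdjacencyGraph") || is.null(graph$membranes))
    stop_input("'graph' must be an AdjacencyGraph with membranes (run create_membranes())")
  if (!all(domains$domains$domain_type %in% names(geom$value_map)))
    stop_logic("domain references a domainType absent from the geometry value map")
  vol <- data.frame(name = names(geom$value_map),
                    dimension = 3L,
                    sampled_value = unname(geom$value_map),
                    stringsAsFactors = FALSE)
  memt <- graph$membrane_types
  dts <- rbind(vol,
               if (nrow(memt)) data.frame(name = memt$name, dimension = 2L,
                                          sampled_value = NA_integer_,
                                          stringsAsFactors = FALSE))
  dvol <- prod(geom$spacing)
  sizes <- vapply(dts$name, function(ty) {
    if (ty %in% domains$domains$domain_type)
      sum(domains$domains$voxel_count[domains$domains$domain_type == ty]) * dvol
    else NA_real_
  }, numeric(1))
  compartments <- data.frame(id = sanitize_sid(dts$name),
                             domain_type = dts$name,
                             spatial_dimensions = dts$dimension,
                             size = sizes, stringsAsFactors = FALSE)
  # membrane domains join the volume domain list, without voxels
  mem <- graph$membranes
  all_domains <- rbind(
    domains$domains,
    if (nrow(mem)) data.frame(id = mem$id, domain_type = mem$membrane_type,
                              sampled_value = NA_integer_, voxel_count = 0L,
                              x = NA_integer_, y = NA_integer_, z = NA_integer_,
                              stringsAsFactors = FALSE))
  structure(list(id = sanitize_sid(id),
                 level = 3L, version = 1L,
                 geometry = geom,
                 domain_types = dts,
                 domains = all_domains,
                 adjacent_domains = graph$adjacent_domains,
                 graph = graph,
                 compartments = compartments,
                 species = data.frame(id = character(), compartment = character(),
                                      initial_concentration = numeric(),
                                      stringsAsFactors = FALSE),
                 parameters = data.frame(id = character(), value = numeric(),
                                         role = character(), species = character(),
                                         axis = character(), stringsAsFactors = FALSE),
                 reactions = list()),
            class = "SpatialModel")
}

#' @export
print.SpatialModel <- function(x, ...) {
  d <- dim(x$geometry$grid)
  cat(sprintf("SpatialModel '%s' (SBML L%dV%d + spatial)\n", x$id, x$level, x$version))
  cat(sprintf("  geometry: %d x %d x %d voxels, %d domainTypes (%d volumes, %d membranes)\n",
              d[1], d[2], d[3], nrow(x$domain_types),
              sum(x$domain_types$dimension == 3L), sum(x$domain_types$dimension == 2L)))
  cat(sprintf("  %d domains, %d adjacentDomains, %d species, %d parameters, %d reactions\n",
              nrow(x$domains), nrow(x$adjacent_domains), nrow(x$species),
              nrow(x$parameters), length(x$reactions)))
  invisible(x)
}

#' Sanitize a name into a valid SBML SId
#'
#' Maps every character outside `[A-Za-z0-9_]` to `_` and prefixes `_` when
#' the result would start with a digit.
#'
#' @param x character vector of candidate identifiers.
#' @return Character vector of valid SIds.
#' @export
sanitize_sid <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", as.character(x))
  ifelse(grepl("^[0-9]", x), paste0("_", x), x)
}

.model_sids <- function(model) {
  c(model$compartments$id, model$species$id, model$parameters$id,
    vapply(model$reactions, `[[`, character(1), "id"))
}

# resolve a compartment given either its SId or a domainType name
.resolve_compartment <- function(model, compartment) {
  if (compartment %in% model$compartments$id) return(compartment)
  hit <- model$compartments$id[model$compartments$domain_type == compartment]
  if (length(hit) == 1L) return(hit)
  stop_input(sprintf("unknown compartment '%s'", compartment))
}

#' Add a molecular species to a spatial model
#'
#' The species is placed in a compartment (a volume for cytosolic species, a
#' membrane compartment such as `PM` for surface-bound species) and flagged
#' as spatially resolved.
#'
#' @param model a `SpatialModel`.
#' @param id unique species identifier.
#' @param compartment compartment SId or domainType name.
#' @param initial_concentration initial concentration (model units).
#' @return The updated `SpatialModel`.
#' @export
add_species <- function(model, id, compartment, initial_concentration = 0) {
  if (!inherits(model, "SpatialModel")) stop_input("'model' must be a SpatialModel")
  id <- sanitize_sid(id)
  if (id %in% .model_sids(model)) stop_input(sprintf("duplicate id '%s'", id))
  comp <- .resolve_compartment(model, compartment)
  model$species <- rbind(model$species,
                         data.frame(id = id, compartment = comp,
                                    initial_concentration = as.numeric(initial_concentration),
                                    stringsAsFactors = FALSE))
  model
}

#' Add a (possibly spatial) parameter to a model
#'
#' Plain parameters (`role = "none"`) are ordinary SBML parameters. Spatial
#' roles attach the corresponding spatial annotation to a target species:
#' `"diffusion"` (isotropic when `axis` is absent), `"advection"` (requires
#' `axis` in `x`/`y`/`z`), or `"boundary-condition"` (requires `axis` naming
#' a coordinate boundary: `Xmin`, `Xmax`, `Ymin`, `Ymax`, `Zmin`, `Zmax`).
#'
#' @param model a `SpatialModel`.
#' @param id unique parameter identifier.
#' @param value numeric value (units consistent with the model).
#' @param role one of `"none"`, `"diffusion"`, `"advection"`,
#'   `"boundary-condition"`.
#' @param species target species id (required for spatial roles).
#' @param axis coordinate axis or boundary, depending on `role`.
#' @return The updated `SpatialModel`.
#' @export
add_spatial_parameter <- function(model, id, value,
                                  role = c("none", "diffusion", "advection",
                                           "boundary-condition"),
                                  species = NA_character_, axis = NA_character_) {
  if (!inherits(model, "SpatialModel")) stop_input("'model' must be a SpatialModel")
  role <- match.arg(role)
  id <- sanitize_sid(id)
  if (id %in% .model_sids(model)) stop_input(sprintf("duplicate id '%s'", id))
  if (role != "none") {
    if (is.na(species) || !species %in% model$species$id)
      stop_input(sprintf("unknown target species '%s' for %s parameter", species, role))
    if (role == "advection") {
      if (is.na(axis) || !axis %in% c("x", "y", "z"))
        stop_input("advection requires 'axis' in {x, y, z}")
    } else if (role == "boundary-condition") {
      if (is.na(axis) || !axis %in% c("Xmin", "Xmax", "Ymin", "Ymax", "Zmin", "Zmax"))
        stop_input("boundary-condition requires 'axis' naming a coordinate boundary (e.g. Xmax)")
    } else if (role == "diffusion") {
      if (!is.na(axis) && !axis %in% c("x", "y", "z"))
        stop_input("diffusion 'axis' must be x, y or z (or absent for isotropic)")
    }
  }
  model$parameters <- rbind(model$parameters,
                            data.frame(id = id, value = as.numeric(value), role = role,
                                       species = as.character(species),
                                       axis = as.character(axis),
                                       stringsAsFactors = FALSE))
  model
}

#' Add a reaction to a spatial model
#'
#' @param model a `SpatialModel`.
#' @param id unique reaction identifier.
#' @param reactants,products character vectors of species ids (either may be
#'   empty, e.g. for degradation).
#' @param rate_expression kinetic-law arithmetic expression over known
#'   species/parameter/compartment ids (`+ - * / ^`, function calls).
#' @param membrane_local `TRUE` marks a transport reaction localized to a
#'   membrane (e.g. export from cytosol to the extracellular space across the
#'   plasma membrane).
#' @param compartment optional compartment SId the reaction is attributed to
#'   (e.g. the membrane compartment for transport).
#' @return The updated `SpatialModel`.
#' @export
add_reaction <- function(model, id, reactants = character(), products = character(),
                         rate_expression, membrane_local = FALSE, compartment = NULL) {
  if (!inherits(model, "SpatialModel")) stop_input("'model' must be a SpatialModel")
  id <- sanitize_sid(id)
  if (id %in% .model_sids(model)) stop_input(sprintf("duplicate id '%s'", id))
  for (sp in c(reactants, products))
    if (!sp %in% model$species$id) stop_input(sprintf("unknown species '%s'", sp))
  known <- c(model$species$id, model$parameters$id, model$compartments$id)
  rate <- normalize_math(rate_expression, known = known)
  comp <- if (!is.null(compartment)) .resolve_compartment(model, compartment) else NA_character_
  model$reactions <- c(model$reactions,
                       list(list(id = id, reactants = as.character(reactants),
                                 products = as.character(products), rate = rate,
                                 membrane_local = isTRUE(membrane_local),
                                 compartment = comp)))
  model
}
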