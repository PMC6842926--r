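SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_SPATIAL_NS <- "http://www.sbml.org/sbml/level3/version1/spatial/version1"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

.num <- function(x) format(x, digits = 15, trim = TRUE, scientific = NA)

.dt_sid <- function(name) paste0(name, "_domainType")

#' Export a spatial model as an SBML Level 3 Version 1 document
#'
#' Serializes the model as SBML L3V1 with the Spatial Processes package
#' declared as required: coordinate components, domainTypes, domains with
#' interior points (voxel-centre physical coordinates), adjacentDomains, a
#' sampledFieldGeometry with one sampledVolume per volume domainType, and
#' the voxel array as an uncompressed sampledField (x fastest, then y, then
#' z), plus compartments, species, parameters and reactions.
#'
#' The model is validated first ([validate_syntax()] and
#' [validate_spatial()]); error-severity issues refuse the export unless
#' `force = TRUE`.
#'
#' @param model a `SpatialModel`.
#' @param path output file path.
#' @param force write even if validation reports errors.
#' @return `path`, invisibly.
#' @seealso [import_sbml()]
#' @export
export_sbml <- function(model, path, force = FALSE) {
  if (!inherits(model, "SpatialModel")) stop_input("'model' must be a SpatialModel")
  issues <- rbind(validate_syntax(model), validate_spatial(model))
  if (!force && any(issues$severity == "error"))
    stop_input(paste0("model fails validation (use force = TRUE to export anyway):\n",
                      paste(format_issues(issues[issues$severity == "error", ]),
                            collapse = "\n")))
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_CORE_NS, "xmlns:spatial" = SBML_SPATIAL_NS,
    level = "3", version = "1", "spatial:required" = "true")
  mdl <- xml2::xml_add_child(doc, "model", id = model$id)

  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (i in seq_len(nrow(model$compartments))) {
    cp <- model$compartments[i, ]
    node <- xml2::xml_add_child(loc, "compartment", id = cp$id,
                                spatialDimensions = as.character(cp$spatial_dimensions),
                                constant = "true")
    if (is.finite(cp$size)) xml2::xml_set_attr(node, "size", .num(cp$size))
    xml2::xml_add_child(node, "spatial:compartmentMapping",
                        "spatial:id" = paste0("cm_", cp$id),
                        "spatial:domainType" = .dt_sid(cp$domain_type),
                        "spatial:unitSize" = "1")
  }

  if (nrow(model$species)) {
    los <- xml2::xml_add_child(mdl, "listOfSpecies")
    for (i in seq_len(nrow(model$species))) {
      sp <- model$species[i, ]
      xml2::xml_add_child(los, "species", id = sp$id, compartment = sp$compartment,
                          initialConcentration = .num(sp$initial_concentration),
                          hasOnlySubstanceUnits = "false", boundaryCondition = "false",
                          constant = "false", "spatial:isSpatial" = "true")
    }
  }

  if (nrow(model$parameters)) {
    lop <- xml2::xml_add_child(mdl, "listOfParameters")
    for (i in seq_len(nrow(model$parameters))) {
      pr <- model$parameters[i, ]
      node <- xml2::xml_add_child(lop, "parameter", id = pr$id,
                                  value = .num(pr$value), constant = "true")
      if (pr$role == "diffusion") {
        dc <- xml2::xml_add_child(node, "spatial:diffusionCoefficient",
                                  "spatial:variable" = pr$species)
        if (!is.na(pr$axis) && pr$axis != "NA") {
          xml2::xml_set_attr(dc, "spatial:type", "anisotropic")
          xml2::xml_set_attr(dc, "spatial:coordinateReference1", .axis_type(pr$axis))
        } else xml2::xml_set_attr(dc, "spatial:type", "isotropic")
      } else if (pr$role == "advection") {
        xml2::xml_add_child(node, "spatial:advectionCoefficient",
                            "spatial:variable" = pr$species,
                            "spatial:coordinate" = .axis_type(pr$axis))
      } else if (pr$role == "boundary-condition") {
        xml2::xml_add_child(node, "spatial:boundaryCondition",
                            "spatial:variable" = pr$species,
                            "spatial:type" = "Dirichlet",
                            "spatial:coordinateBoundary" = pr$axis)
      }
    }
  }

  if (length(model$reactions)) {
    lor <- xml2::xml_add_child(mdl, "listOfReactions")
    for (rx in model$reactions) {
      node <- xml2::xml_add_child(lor, "reaction", id = rx$id,
                                  reversible = "false", fast = "false",
                                  "spatial:isLocal" = if (rx$membrane_local) "true" else "false")
      if (!is.na(rx$compartment)) xml2::xml_set_attr(node, "compartment", rx$compartment)
      if (length(rx$reactants)) {
        lr <- xml2::xml_add_child(node, "listOfReactants")
        for (sp in rx$reactants)
          xml2::xml_add_child(lr, "speciesReference", species = sp,
                              stoichiometry = "1", constant = "true")
      }
      if (length(rx$products)) {
        lp <- xml2::xml_add_child(node, "listOfProducts")
        for (sp in rx$products)
          xml2::xml_add_child(lp, "speciesReference", species = sp,
                              stoichiometry = "1", constant = "true")
      }
      kl <- xml2::xml_add_child(node, "kineticLaw")
      math <- xml2::read_xml(math_to_mathml(rx$rate))
      xml2::xml_add_child(kl, math)
    }
  }

  .write_geometry(mdl, model)
  xml2::write_xml(doc, path)
  invisible(path)
}

.axis_type <- function(axis) {
  c(x = "cartesianX", y = "cartesianY", z = "cartesianZ")[[axis]]
}

.write_geometry <- function(mdl, model) {
  geom <- model$geometry
  dims <- dim(geom$grid)
  sp <- geom$spacing
  g <- xml2::xml_add_child(mdl, "spatial:geometry",
                           "spatial:coordinateSystem" = "cartesian")
  lcc <- xml2::xml_add_child(g, "spatial:listOfCoordinateComponents")
  axes <- c("x", "y", "z")
  for (a in 1:3) {
    cc <- xml2::xml_add_child(lcc, "spatial:coordinateComponent",
                              "spatial:id" = axes[a],
                              "spatial:type" = .axis_type(axes[a]))
    xml2::xml_add_child(cc, "spatial:boundaryMin",
                        "spatial:id" = paste0(toupper(axes[a]), "min"),
                        "spatial:value" = "0")
    xml2::xml_add_child(cc, "spatial:boundaryMax",
                        "spatial:id" = paste0(toupper(axes[a]), "max"),
                        "spatial:value" = .num(dims[a] * sp[a]))
  }
  ldt <- xml2::xml_add_child(g, "spatial:listOfDomainTypes")
  for (i in seq_len(nrow(model$domain_types))) {
    dt <- model$domain_types[i, ]
    xml2::xml_add_child(ldt, "spatial:domainType",
                        "spatial:id" = .dt_sid(dt$name),
                        "spatial:spatialDimensions" = as.character(dt$dimension))
  }
  ld <- xml2::xml_add_child(g, "spatial:listOfDomains")
  for (i in seq_len(nrow(model$domains))) {
    dm <- model$domains[i, ]
    node <- xml2::xml_add_child(ld, "spatial:domain",
                                "spatial:id" = dm$id,
                                "spatial:domainType" = .dt_sid(dm$domain_type))
    if (!is.na(dm$x)) {
      lip <- xml2::xml_add_child(node, "spatial:listOfInteriorPoints")
      xml2::xml_add_child(lip, "spatial:interiorPoint",
                          "spatial:coord1" = .num((dm$x + 0.5) * sp[1]),
                          "spatial:coord2" = .num((dm$y + 0.5) * sp[2]),
                          "spatial:coord3" = .num((dm$z + 0.5) * sp[3]))
    }
  }
  if (nrow(model$adjacent_domains)) {
    lad <- xml2::xml_add_child(g, "spatial:listOfAdjacentDomains")
    for (i in seq_len(nrow(model$adjacent_domains))) {
      ad <- model$adjacent_domains[i, ]
      xml2::xml_add_child(lad, "spatial:adjacentDomains",
                          "spatial:id" = ad$id,
                          "spatial:domain1" = ad$domain1,
                          "spatial:domain2" = ad$domain2)
    }
  }
  lgd <- xml2::xml_add_child(g, "spatial:listOfGeometryDefinitions")
  sfg <- xml2::xml_add_child(lgd, "spatial:sampledFieldGeometry",
                             "spatial:id" = "sampled_field_geometry",
                             "spatial:isActive" = "true",
                             "spatial:sampledField" = "sampled_field")
  lsv <- xml2::xml_add_child(sfg, "spatial:listOfSampledVolumes")
  vols <- model$domain_types[model$domain_types$dimension == 3L, ]
  for (i in seq_len(nrow(vols))) {
    xml2::xml_add_child(lsv, "spatial:sampledVolume",
                        "spatial:id" = paste0("sv_", vols$name[i]),
                        "spatial:domainType" = .dt_sid(vols$name[i]),
                        "spatial:sampledValue" = as.character(vols$sampled_value[i]))
  }
  lsf <- xml2::xml_add_child(g, "spatial:listOfSampledFields")
  sf <- xml2::xml_add_child(lsf, "spatial:sampledField",
                            "spatial:id" = "sampled_field",
                            "spatial:dataType" = "uint8",
                            "spatial:numSamples1" = as.character(dims[1]),
                            "spatial:numSamples2" = as.character(dims[2]),
                            "spatial:numSamples3" = as.character(dims[3]),
                            "spatial:interpolationType" = "nearestNeighbor",
                            "spatial:compression" = "uncompressed",
                            "spatial:samplesLength" = as.character(prod(dims)))
  # voxel order: x fastest, then y, then z (R array linearization)
  xml2::xml_set_text(sf, paste(as.vector(geom$grid), collapse = " "))
}

#' Import a spatial SBML document
#'
#' Reads an SBML Level 3 Version 1 file carrying the Spatial Processes
#' package and reconstructs the full `SpatialModel`, including the voxel
#' grid decoded from the sampled field, the domainType/domain/adjacency
#' structure, and all species, parameters and reactions. Documents of the
#' wrong level/version, or without the spatial extension, are rejected.
#'
#' @param path path to an SBML L3V1 + spatial XML file.
#' @return A `SpatialModel`.
#' @export
import_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_input(sprintf("malformed XML in '%s': %s",
                                                         path, conditionMessage(e))))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml")
    stop_input(sprintf("'%s' is not an SBML document (root element '%s')",
                       path, xml2::xml_name(root)))
  lev <- xml2::xml_attr(root, "level"); ver <- xml2::xml_attr(root, "version")
  if (!identical(lev, "3") || !identical(ver, "1"))
    stop_input(sprintf("unsupported SBML Level %s Version %s: only Level 3 Version 1 is handled",
                       lev, ver))
  ns <- xml2::xml_ns(doc)
  if (!SBML_SPATIAL_NS %in% unlist(ns))
    stop_input("document does not declare the SBML spatial package; only spatial models can be edited")
  sp_prefix <- names(ns)[match(SBML_SPATIAL_NS, unlist(ns))]
  core_prefix <- names(ns)[match(SBML_CORE_NS, unlist(ns))]
  q <- function(node, xpath) xml2::xml_find_all(node, xpath, ns)
  # rewrite generic prefixes in xpaths
  X <- function(p) gsub("s:", paste0(sp_prefix, ":"),
                        gsub("c:", paste0(core_prefix, ":"), p, fixed = TRUE),
                        fixed = TRUE)
  geom_node <- q(root, X(".//s:geometry"))
  if (!length(geom_node)) stop_input("spatial geometry element missing")
  geom_node <- geom_node[[1]]

  sf <- q(geom_node, X(".//s:sampledField"))
  if (!length(sf)) stop_input("sampledField missing")
  sf <- sf[[1]]
  if (!identical(xml2::xml_attr(sf, "compression"), "uncompressed"))
    stop_input("only uncompressed sampled fields are supported")
  dims <- as.integer(c(xml2::xml_attr(sf, "numSamples1"),
                       xml2::xml_attr(sf, "numSamples2"),
                       xml2::xml_attr(sf, "numSamples3")))
  vals <- as.integer(strsplit(trimws(xml2::xml_text(sf)), "\\s+")[[1]])
  if (length(vals) != prod(dims))
    stop_input(sprintf("sampledField declares %d samples but holds %d",
                       prod(dims), length(vals)))
  grid <- array(vals, dims)

  cc <- q(geom_node, X(".//s:coordinateComponent"))
  bounds <- numeric(3)
  for (node in cc) {
    ty <- xml2::xml_attr(node, "type")
    ax <- match(ty, c("cartesianX", "cartesianY", "cartesianZ"))
    mx <- q(node, X("./s:boundaryMax"))
    bounds[ax] <- as.numeric(xml2::xml_attr(mx[[1]], "value"))
  }
  spacing <- bounds / dims

  dt_nodes <- q(geom_node, X(".//s:domainType"))
  dt <- data.frame(
    sid = xml2::xml_attr(dt_nodes, "id"),
    dimension = as.integer(xml2::xml_attr(dt_nodes, "spatialDimensions")),
    stringsAsFactors = FALSE)
  dt$name <- sub("_domainType$", "", dt$sid)

  sv_nodes <- q(geom_node, X(".//s:sampledVolume"))
  sv <- data.frame(
    dt_sid = xml2::xml_attr(sv_nodes, "domainType"),
    value = as.integer(xml2::xml_attr(sv_nodes, "sampledValue")),
    stringsAsFactors = FALSE)
  dt$sampled_value <- sv$value[match(dt$sid, sv$dt_sid)]
  vols <- dt[dt$dimension == 3L, ]
  vols <- vols[order(vols$sampled_value), ]
  value_map <- stats::setNames(vols$sampled_value, vols$name)
  depth_order <- vols$name
  geom <- structure(list(grid = grid, value_map = value_map,
                         spacing = spacing, depth_order = depth_order),
                    class = "LabeledGeometry")

  d_nodes <- q(geom_node, X(".//s:domain"))
  doms <- data.frame(
    id = xml2::xml_attr(d_nodes, "id"),
    domain_type = sub("_domainType$", "",
                      xml2::xml_attr(d_nodes, "domainType")),
    stringsAsFactors = FALSE)
  doms$sampled_value <- value_map[doms$domain_type]
  ip <- t(vapply(d_nodes, function(n) {
    p <- q(n, X(".//s:interiorPoint"))
    if (!length(p)) return(c(NA_real_, NA_real_, NA_real_))
    as.numeric(c(xml2::xml_attr(p[[1]], "coord1"),
                 xml2::xml_attr(p[[1]], "coord2"),
                 xml2::xml_attr(p[[1]], "coord3")))
  }, numeric(3)))
  doms$x <- as.integer(floor(ip[, 1] / spacing[1]))
  doms$y <- as.integer(floor(ip[, 2] / spacing[2]))
  doms$z <- as.integer(floor(ip[, 3] / spacing[3]))
  vol_rows <- doms$domain_type %in% names(value_map)
  doms$voxel_count <- 0L
  # recount voxels per volume domain by re-labeling the imported grid
  dset <- label_domains(geom)
  m <- match(doms$id, dset$domains$id)
  hit <- !is.na(m)
  doms$voxel_count[hit] <- dset$domains$voxel_count[m[hit]]
  doms <- doms[, c("id", "domain_type", "sampled_value", "voxel_count", "x", "y", "z")]

  ad_nodes <- q(geom_node, X(".//s:adjacentDomains"))
  adj <- data.frame(
    id = xml2::xml_attr(ad_nodes, "id"),
    domain1 = xml2::xml_attr(ad_nodes, "domain1"),
    domain2 = xml2::xml_attr(ad_nodes, "domain2"),
    stringsAsFactors = FALSE)

  graph <- .graph_from_import(doms, dt, adj, value_map)

  comp_nodes <- q(root, X(".//c:compartment"))
  compartments <- data.frame(
    id = xml2::xml_attr(comp_nodes, "id"),
    domain_type = vapply(comp_nodes, function(n) {
      cm <- q(n, X("./s:compartmentMapping"))
      if (length(cm)) sub("_domainType$", "", xml2::xml_attr(cm[[1]], "domainType"))
      else NA_character_
    }, character(1)),
    spatial_dimensions = as.integer(xml2::xml_attr(comp_nodes, "spatialDimensions")),
    size = suppressWarnings(as.numeric(xml2::xml_attr(comp_nodes, "size"))),
    stringsAsFactors = FALSE)

  sp_nodes <- q(root, X(".//c:species"))
  species <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    initial_concentration = suppressWarnings(
      as.numeric(xml2::xml_attr(sp_nodes, "initialConcentration"))),
    stringsAsFactors = FALSE)
  if (!nrow(species))
    species <- data.frame(id = character(), compartment = character(),
                          initial_concentration = numeric(), stringsAsFactors = FALSE)

  par_nodes <- q(root, X(".//c:parameter"))
  parameters <- do.call(rbind, c(list(
    data.frame(id = character(), value = numeric(), role = character(),
               species = character(), axis = character(), stringsAsFactors = FALSE)),
    lapply(par_nodes, function(n) {
      role <- "none"; spv <- NA_character_; axis <- NA_character_
      dc <- q(n, X("./s:diffusionCoefficient"))
      av <- q(n, X("./s:advectionCoefficient"))
      bc <- q(n, X("./s:boundaryCondition"))
      if (length(dc)) {
        role <- "diffusion"; spv <- xml2::xml_attr(dc[[1]], "variable")
        cr <- xml2::xml_attr(dc[[1]], "coordinateReference1")
        if (!is.na(cr)) axis <- c(cartesianX = "x", cartesianY = "y", cartesianZ = "z")[[cr]]
      } else if (length(av)) {
        role <- "advection"; spv <- xml2::xml_attr(av[[1]], "variable")
        axis <- c(cartesianX = "x", cartesianY = "y",
                  cartesianZ = "z")[[xml2::xml_attr(av[[1]], "coordinate")]]
      } else if (length(bc)) {
        role <- "boundary-condition"; spv <- xml2::xml_attr(bc[[1]], "variable")
        axis <- xml2::xml_attr(bc[[1]], "coordinateBoundary")
      }
      data.frame(id = xml2::xml_attr(n, "id"),
                 value = as.numeric(xml2::xml_attr(n, "value")),
                 role = role, species = spv, axis = axis, stringsAsFactors = FALSE)
    })))

  rx_nodes <- q(root, X(".//c:reaction"))
  reactions <- lapply(rx_nodes, function(n) {
    math <- q(n, X(".//c:kineticLaw/*[local-name() = 'math']"))
    rate <- if (length(math)) mathml_to_math(math[[1]]) else NA_character_
    list(id = xml2::xml_attr(n, "id"),
         reactants = xml2::xml_attr(q(n, X("./c:listOfReactants/c:speciesReference")), "species"),
         products = xml2::xml_attr(q(n, X("./c:listOfProducts/c:speciesReference")), "species"),
         rate = rate,
         membrane_local = identical(xml2::xml_attr(n, "isLocal"), "true"),
         compartment = xml2::xml_attr(n, "compartment"))
  })

  mdl_node <- q(root, X("./c:model"))
  structure(list(id = if (length(mdl_node)) xml2::xml_attr(mdl_node[[1]], "id") else "model",
                 level = 3L, version = 1L,
                 geometry = geom,
                 domain_types = dt[, c("name", "dimension", "sampled_value")],
                 domains = doms,
                 adjacent_domains = adj,
                 graph = graph,
                 compartments = compartments,
                 species = species,
                 parameters = parameters,
                 reactions = reactions),
            class = "SpatialModel")
}

# rebuild the AdjacencyGraph (without face counts) from imported records
.graph_from_import <- function(doms, dt, adj, value_map) {
  vol_doms <- doms[doms$domain_type %in% names(value_map), ]
  mem_doms <- doms[!doms$domain_type %in% names(value_map), ]
  membranes <- data.frame(id = character(), membrane_type = character(),
                          inner = character(), outer = character(),
                          stringsAsFactors = FALSE)
  edges <- data.frame(domain1 = character(), domain2 = character(),
                      faces = integer(), stringsAsFactors = FALSE)
  if (nrow(mem_doms)) {
    rows <- lapply(mem_doms$id, function(mid) {
      nb <- adj$domain2[adj$domain1 == mid]
      if (length(nb) != 2L) return(NULL)
      v <- value_map[doms$domain_type[match(nb, doms$id)]]
      inner <- nb[which.max(v)]; outer <- nb[which.min(v)]
      data.frame(id = mid,
                 membrane_type = mem_doms$domain_type[mem_doms$id == mid],
                 inner = inner, outer = outer, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) {
      membranes <- do.call(rbind, rows)
      edges <- data.frame(domain1 = pmin(membranes$inner, membranes$outer),
                          domain2 = pmax(membranes$inner, membranes$outer),
                          faces = NA_integer_, stringsAsFactors = FALSE)
      edges <- edges[order(edges$domain1, edges$domain2), ]
      rownames(edges) <- NULL
    }
  }
  mtypes <- unique(data.frame(
    name = membranes$membrane_type,
    inner_type = doms$domain_type[match(membranes$inner, doms$id)],
    outer_type = doms$domain_type[match(membranes$outer, doms$id)],
    stringsAsFactors = FALSE))
  if (nrow(mtypes)) { mtypes <- mtypes[order(mtypes$name), ]; rownames(mtypes) <- NULL }
  structure(list(nodes = vol_doms, edges = edges,
                 membrane_types = mtypes, membranes = membranes,
                 adjacent_domains = adj),
            class = "AdjacencyGraph")
}
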