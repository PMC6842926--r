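issue <- function(severity, rule, id, message) {
  data.frame(severity = severity, rule = rule, id = id, message = message,
             stringsAsFactors = FALSE)
}

no_issues <- function() {
  data.frame(severity = character(), rule = character(), id = character(),
             message = character(), stringsAsFactors = FALSE)
}

#' Format validation issues for printing
#'
#' @param issues an issue data frame from [validate_syntax()] or
#'   [validate_spatial()].
#' @return Character vector, one `"SEVERITY RULE id: message"` line per issue.
#' @export
format_issues <- function(issues) {
  if (!nrow(issues)) return(character(0))
  sprintf("%s %s %s: %s", toupper(issues$severity), issues$rule,
          issues$id, issues$message)
}

#' Syntactic validation of a spatial model or SBML file
#'
#' Structural checks on the SBML core constructs: well-formed XML and
#' declared Level 3 Version 1 (for file input), unique SIds, resolvable
#' references (species to compartment, reactions to species, spatial
#' parameters to their target species), and parseable kinetic-law
#' expressions. Issues are returned as data, never raised.
#'
#' @param x a `SpatialModel` or a path to an SBML XML file.
#' @return Issue data frame (`severity`, `rule`, `id`, `message`); zero rows
#'   means the model passes.
#' @export
validate_syntax <- function(x) {
  if (is.character(x)) {
    model <- tryCatch(import_sbml(x), error = function(e) e)
    if (inherits(model, "error"))
      return(issue("error", "xml-parse", basename(x), conditionMessage(model)))
    return(validate_syntax(model))
  }
  if (!inherits(x, "SpatialModel")) stop_input("'x' must be a SpatialModel or a file path")
  model <- x
  iss <- no_issues()
  if (model$level != 3L || model$version != 1L)
    iss <- rbind(iss, issue("error", "sbml-level-version", model$id,
                            sprintf("declared Level %d Version %d; expected Level 3 Version 1",
                                    model$level, model$version)))
  sids <- c(.model_sids(model), .dt_sid(model$domain_types$name), model$domains$id)
  dup <- unique(sids[duplicated(sids)])
  for (d in dup)
    iss <- rbind(iss, issue("error", "sid-unique", d, sprintf("duplicate SId '%s'", d)))
  bad_comp <- setdiff(model$species$compartment, model$compartments$id)
  for (i in which(model$species$compartment %in% bad_comp))
    iss <- rbind(iss, issue("error", "species-compartment", model$species$id[i],
                            sprintf("species '%s' references unknown compartment '%s'",
                                    model$species$id[i], model$species$compartment[i])))
  spatial_par <- model$parameters[model$parameters$role != "none", ]
  for (i in seq_len(nrow(spatial_par))) {
    if (!spatial_par$species[i] %in% model$species$id)
      iss <- rbind(iss, issue("error", "parameter-target", spatial_par$id[i],
                              sprintf("%s parameter '%s' targets unknown species '%s'",
                                      spatial_par$role[i], spatial_par$id[i],
                                      spatial_par$species[i])))
  }
  known <- c(model$species$id, model$parameters$id, model$compartments$id)
  for (rx in model$reactions) {
    for (sp in c(rx$reactants, rx$products))
      if (!sp %in% model$species$id)
        iss <- rbind(iss, issue("error", "reaction-species", rx$id,
                                sprintf("reaction '%s' references unknown species '%s'",
                                        rx$id, sp)))
    ok <- tryCatch({ normalize_math(rx$rate, known = known); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok))
      iss <- rbind(iss, issue("error", "math-parse", rx$id, ok))
  }
  iss
}

#' Semantic validation of the spatial constructs
#'
#' The built-in spatial validator: sampled values pairwise distinct; every
#' grid value mapped by a sampledVolume; every volume domainType has at
#' least one domain and exactly one compartment mapping; adjacentDomains
#' reference existing domains; every membrane domain has exactly two
#' adjacentDomains records; membrane dimension is 2 (= volume dimension - 1);
#' each interior point lies on a voxel of its domain's sampled value;
#' coordinate bounds match grid extent times spacing. Biologically
#' impossible adjacencies (an organelle touching a region other than its
#' direct parent, e.g. nucleus against extracellular matrix) are reported as
#' warnings.
#'
#' @param model a `SpatialModel` with geometry.
#' @return Issue data frame; zero error-severity rows means the spatial
#'   structure is consistent.
#' @export
validate_spatial <- function(model) {
  if (!inherits(model, "SpatialModel")) stop_input("'model' must be a SpatialModel")
  iss <- no_issues()
  geom <- model$geometry
  vols <- model$domain_types[model$domain_types$dimension == 3L, ]
  mems <- model$domain_types[model$domain_types$dimension == 2L, ]

  dupv <- unique(vols$sampled_value[duplicated(vols$sampled_value)])
  for (v in dupv)
    iss <- rbind(iss, issue("error", "sampled-value-unique",
                            paste(vols$name[vols$sampled_value == v], collapse = ","),
                            sprintf("sampled value %d assigned to more than one domainType", v)))

  grid_vals <- sort(unique(as.vector(geom$grid)))
  orphan <- setdiff(grid_vals, vols$sampled_value)
  for (v in orphan)
    iss <- rbind(iss, issue("error", "grid-value-mapped", as.character(v),
                            sprintf("grid value %d has no sampledVolume/domainType", v)))

  for (ty in vols$name) {
    nd <- sum(model$domains$domain_type == ty)
    if (nd < 1L)
      iss <- rbind(iss, issue("error", "domaintype-nonempty", ty,
                              sprintf("volume domainType '%s' has no domain", ty)))
    nc <- sum(model$compartments$domain_type == ty, na.rm = TRUE)
    if (nc != 1L)
      iss <- rbind(iss, issue("error", "compartment-mapping", ty,
                              sprintf("domainType '%s' maps to %d compartments; expected exactly 1",
                                      ty, nc)))
  }
  for (ty in mems$name) {
    nc <- sum(model$compartments$domain_type == ty, na.rm = TRUE)
    if (nc != 1L)
      iss <- rbind(iss, issue("error", "compartment-mapping", ty,
                              sprintf("domainType '%s' maps to %d compartments; expected exactly 1",
                                      ty, nc)))
  }

  for (i in seq_len(nrow(model$adjacent_domains))) {
    ad <- model$adjacent_domains[i, ]
    for (dref in c(ad$domain1, ad$domain2))
      if (!dref %in% model$domains$id)
        iss <- rbind(iss, issue("error", "adjacent-ref", ad$id,
                                sprintf("adjacentDomains '%s' references unknown domain '%s'",
                                        ad$id, dref)))
  }

  mem_domains <- model$domains[model$domains$domain_type %in% mems$name, ]
  for (mid in mem_domains$id) {
    n <- sum(model$adjacent_domains$domain1 == mid | model$adjacent_domains$domain2 == mid)
    if (n != 2L)
      iss <- rbind(iss, issue("error", "membrane-two-adjacent", mid,
                              sprintf("membrane domain '%s' has %d adjacentDomains records; expected 2",
                                      mid, n)))
  }

  bad_dim <- model$domain_types[!model$domain_types$dimension %in% c(2L, 3L), ]
  for (i in seq_len(nrow(bad_dim)))
    iss <- rbind(iss, issue("error", "membrane-dimension", bad_dim$name[i],
                            sprintf("domainType '%s' has dimension %d; membranes must be 2, volumes 3",
                                    bad_dim$name[i], bad_dim$dimension[i])))

  dims <- dim(geom$grid)
  value_of <- stats::setNames(vols$sampled_value, vols$name)
  vol_doms <- model$domains[model$domains$domain_type %in% vols$name, ]
  for (i in seq_len(nrow(vol_doms))) {
    dm <- vol_doms[i, ]
    if (is.na(dm$x)) {
      iss <- rbind(iss, issue("error", "interior-point", dm$id,
                              sprintf("volume domain '%s' has no interior point", dm$id)))
      next
    }
    if (dm$x < 0L || dm$x >= dims[1] || dm$y < 0L || dm$y >= dims[2] ||
        dm$z < 0L || dm$z >= dims[3]) {
      iss <- rbind(iss, issue("error", "interior-point", dm$id,
                              sprintf("interior point of '%s' lies outside the grid", dm$id)))
      next
    }
    v <- geom$grid[dm$x + 1L, dm$y + 1L, dm$z + 1L]
    if (v != value_of[[dm$domain_type]])
      iss <- rbind(iss, issue("error", "interior-point", dm$id,
                              sprintf("interior point of '%s' sits on value %d, not its sampled value %d",
                                      dm$id, v, value_of[[dm$domain_type]])))
  }

  # coordinate bounds are extent * spacing by construction; verify the
  # stored spacing is positive and finite (bounds are derived on export)
  if (any(!is.finite(geom$spacing)) || any(geom$spacing <= 0))
    iss <- rbind(iss, issue("error", "coordinate-bounds", model$id,
                            "voxel spacing must be positive and finite"))

  hier <- structure(geom$depth_order, depths = attr(geom$depth_order, "depths"))
  warns <- tryCatch(check_biology(model$graph, hier), error = function(e) character(0))
  for (w in warns)
    iss <- rbind(iss, issue("warning", "biological-consistency", model$id, w))
  iss
}
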