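#' Convert segmented component masks into a spatial SBML model
#'
#' The full pipeline: binarize each mask, fill holes, derive (or take) the
#' containment hierarchy, fill gaps between each component and its parent,
#' interpolate anisotropic stacks, resolve overlaps (innermost wins), merge
#' into one grayscale geometry, label domains, resolve adjacency, create
#' membranes, check biological consistency (warnings), and assemble the SBML
#' model.
#'
#' @param masks named list of [image_stack()]s, one per cellular component.
#' @param nesting optional character vector of mask names from outermost to
#'   innermost (a strict chain); when `NULL` the hierarchy is derived from
#'   containment of the masks.
#' @param fill logical; apply hole and gap filling (default `TRUE`).
#' @param interpolate logical; apply nearest-neighbour z-interpolation to
#'   anisotropic stacks (default `TRUE`).
#' @param id SBML model id.
#' @return A `SpatialModel` ready for editing and [export_sbml()].
#' @examples
#' m <- convert_images(nested_spheres(c(16, 16, 16), radii = c(6, 3)))
#' m$geometry$value_map
#' @export
convert_images <- function(masks, nesting = NULL, fill = TRUE,
                           interpolate = TRUE, id = "spatial_model") {
  if (length(masks)) {
    if (is.null(names(masks)) || any(names(masks) == ""))
      stop_input("'masks' must be a named list (one name per cellular component)")
    masks <- lapply(masks, ensure_binary)
    if (fill) masks <- lapply(masks, fill_holes)
  }
  hier <- if (is.null(nesting)) {
    containment_hierarchy(masks)
  } else {
    if (!setequal(nesting, names(masks)))
      stop_input("'nesting' must list every mask name exactly once")
    structure(c("EC", nesting), depths = seq_along(c("EC", nesting)) - 1L)
  }
  if (fill && length(masks) > 1L) {
    parent <- .parents_of(masks, hier)
    for (nm in names(masks)) {
      p <- parent[[nm]]
      if (!is.na(p)) {
        res <- fill_gap(masks[[p]], masks[[nm]])
        masks[[p]] <- res$outer
      }
    }
  }
  if (interpolate && length(masks)) masks <- lapply(masks, interpolate_z)
  inner <- setdiff(hier, hier[[1]])
  if (length(masks) > 1L) masks <- resolve_overlap(masks, order = inner)
  geom <- merge_masks(masks, order = hier)
  domains <- label_domains(geom)
  graph <- detect_adjacency(geom, domains)
  graph <- create_membranes(graph, geom$depth_order)
  for (w in check_biology(graph, hier))
    warning("biologically impossible adjacency: ", w, call. = FALSE)
  model <- build_model(geom, domains, graph, id = id)
  model$geometry$depth_order <- hier
  model
}

# deepest mask strictly containing each mask (NA when the parent is EC)
.parents_of <- function(masks, hier) {
  filled <- lapply(masks, function(m) fg(fill_holes(m)))
  counts <- vapply(filled, sum, numeric(1))
  out <- stats::setNames(rep(NA_character_, length(masks)), names(masks))
  for (nm in names(masks)) {
    sup <- Filter(function(o) {
      o != nm && counts[[o]] > counts[[nm]] &&
        sum(filled[[o]] & filled[[nm]]) == counts[[nm]]
    }, names(masks))
    if (length(sup)) out[[nm]] <- sup[which.min(counts[sup])]
  }
  out
}
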