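#' Derive the containment hierarchy of component masks
#'
#' Orders the components from outermost to innermost by strict containment of
#' their *filled* regions (a mask's region together with everything it
#' encloses), so the result is the same whether masks are solid or shells
#' already carved by [resolve_overlap()]. The extracellular background `"EC"`
#' is implicit at depth 0. Siblings at equal depth are ordered by descending
#' voxel count for deterministic ids.
#'
#' @param masks named list of binary [image_stack()]s with identical extents.
#' @param ec name used for the implicit extracellular domainType.
#' @return Character vector of names ordered outermost to innermost, starting
#'   with `ec`, with an integer attribute `"depths"` giving each entry's true
#'   containment depth (EC = 0).
#' @examples
#' fx <- nested_spheres(c(24, 24, 24))
#' containment_hierarchy(fx)
#' @export
containment_hierarchy <- function(masks, ec = "EC") {
  if (!length(masks)) {
    return(structure(ec, depths = 0L))
  }
  if (is.null(names(masks)) || anyDuplicated(names(masks)))
    stop_input("'masks' must be a uniquely named list")
  for (nm in names(masks)) assert_binary(masks[[nm]], nm)
  nms <- names(masks)
  filled <- lapply(masks, function(m) fg(fill_holes(m)))
  counts <- vapply(filled, sum, numeric(1))
  n <- length(nms)
  contains <- matrix(FALSE, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    inter <- sum(filled[[i]] & filled[[j]])
    if (inter == 0) next
    if (inter == counts[j] && counts[j] < counts[i]) {
      contains[i, j] <- TRUE        # i strictly contains j
    } else if (inter == counts[i] && counts[i] < counts[j]) {
      # j contains i: recorded when the roles are swapped
    } else {
      stop_input(sprintf(
        "masks '%s' and '%s' overlap with neither strictly containing the other; fix the segmentation or the nesting order",
        nms[i], nms[j]))
    }
  }
  depth <- as.integer(colSums(contains)) + 1L   # EC is depth 0
  ord <- order(depth, -counts, nms)
  structure(c(ec, nms[ord]), depths = c(0L, unname(depth[ord])))
}

#' Merge disjoint component masks into one grayscale geometry
#'
#' Combines the corrected masks into a single grayscale voxel grid, assigning
#' a distinct 8-bit sampled value to each volume domainType: with `N` volume
#' domainTypes (including the extracellular background at value 0), the type
#' at position `d` of the depth order receives `d * floor(255/N)`. For the
#' two-mask cytosol/nucleus case this yields the values 0, 85 and 170.
#'
#' @param masks named list of pairwise-disjoint binary [image_stack()]s (see
#'   [resolve_overlap()]).
#' @param order depth order as returned by [containment_hierarchy()]; its
#'   first entry is the extracellular name.
#' @return An object of class `LabeledGeometry`: list with `grid` (3D integer
#'   array of sampled values), `value_map` (named integer vector, domainType
#'   name to sampled value), `spacing`, and `depth_order`.
#' @export
merge_masks <- function(masks, order = containment_hierarchy(masks)) {
  if (length(order) < 1L) stop_input("'order' must at least name the extracellular type")
  ec <- order[[1]]
  inner <- setdiff(order, ec)
  if (!setequal(inner, names(masks)))
    stop_input("'order' (beyond EC) must be a permutation of names(masks)")
  n_types <- length(order)
  step <- 255L %/% n_types
  if (step < 1L) stop_input("more than 255 volume domainTypes cannot be encoded in 8-bit values")
  value_map <- stats::setNames((seq_len(n_types) - 1L) * step, order)
  if (!length(masks)) {
    return(structure(list(grid = array(0L, c(1L, 1L, 1L)),
                          value_map = value_map, spacing = c(1, 1, 1),
                          depth_order = order),
                     class = "LabeledGeometry"))
  }
  for (nm in inner) assert_binary(masks[[nm]], nm)
  dims <- dim(masks[[inner[1]]]$voxels)
  grid <- array(0L, dims)
  for (nm in inner) {
    if (!identical(dim(masks[[nm]]$voxels), dims))
      stop_input("all masks must have identical extents")
    grid[fg(masks[[nm]])] <- value_map[[nm]]
  }
  structure(list(grid = grid, value_map = value_map,
                 spacing = masks[[inner[1]]]$spacing, depth_order = order),
            class = "LabeledGeometry")
}

#' @export
print.LabeledGeometry <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("LabeledGeometry: %d x %d x %d voxels, spacing (%g, %g, %g)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat("  sampled values:",
      paste(sprintf("%s=%d", names(x$value_map), x$value_map), collapse = ", "), "\n")
  invisible(x)
}

#' Label contiguous regions of each domainType as domains
#'
#' Every maximal 26-connected (8-connected in 2D) region of one sampled value
#' is one domain; the extracellular complement is labeled too. Ordinals
#' within a domainType are assigned by descending voxel count, ties broken by
#' the lexicographically smallest minimum voxel coordinate, giving
#' deterministic ids such as `Cyt0`, `Nuc0`, `Nuc1`.
#'
#' @param geom a [merge_masks()] `LabeledGeometry`.
#' @param connectivity 26 (default) or 6; voxel connectivity defining a
#'   contiguous region.
#' @return An object of class `DomainSet`: list with `domains` (data frame:
#'   `id`, `domain_type`, `sampled_value`, `voxel_count`, `x`, `y`, `z` — the
#'   interior point in 0-based voxel indices) and `label_grid` (integer array
#'   mapping each voxel to the row of its domain).
#' @export
label_domains <- function(geom, connectivity = 26L) {
  if (!inherits(geom, "LabeledGeometry")) stop_input("'geom' must be a LabeledGeometry")
  dims <- dim(geom$grid)
  label_grid <- array(0L, dims)
  rows <- list()
  next_label <- 0L
  for (ty in geom$depth_order) {
    val <- geom$value_map[[ty]]
    mask <- geom$grid == val
    if (!any(mask)) next
    comp <- .label_components(mask, connectivity)
    k <- max(comp)
    meta <- lapply(seq_len(k), function(i) {
      idx <- which(comp == i)
      co <- arrayInd(idx, dims)
      lex <- order(co[, 1], co[, 2], co[, 3])[1]
      list(idx = idx, count = length(idx), lexmin = co[lex, ])
    })
    ord <- order(-vapply(meta, `[[`, numeric(1), "count"),
                 vapply(meta, function(m) m$lexmin[1], numeric(1)),
                 vapply(meta, function(m) m$lexmin[2], numeric(1)),
                 vapply(meta, function(m) m$lexmin[3], numeric(1)))
    dist <- .value_distance(geom$grid, val)
    for (r in seq_along(ord)) {
      m <- meta[[ord[r]]]
      next_label <- next_label + 1L
      label_grid[m$idx] <- next_label
      ip <- .farthest_voxel(m$idx, dist, dims)
      rows[[next_label]] <- data.frame(
        id = paste0(ty, r - 1L), domain_type = ty,
        sampled_value = val, voxel_count = m$count,
        x = ip[1] - 1L, y = ip[2] - 1L, z = ip[3] - 1L,
        stringsAsFactors = FALSE)
    }
  }
  domains <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), domain_type = character(),
               sampled_value = integer(), voxel_count = integer(),
               x = integer(), y = integer(), z = integer())
  structure(list(domains = domains, label_grid = label_grid),
            class = "DomainSet")
}

#' @export
print.DomainSet <- function(x, ...) {
  cat("DomainSet with", nrow(x$domains), "domains:\n")
  print(x$domains, row.names = FALSE)
  invisible(x)
}

# city-block distance from every voxel to the nearest voxel whose grid value
# differs from `val`; NA when the whole grid has that value
.value_distance <- function(grid, val) {
  .bfs_distance(which(grid != val), dim(grid))
}

# among the voxels `idx`, the one with maximal distance; ties broken by
# lexicographic (x, y, z); if all distances are NA (uniform grid), the
# lexicographically first voxel
.farthest_voxel <- function(idx, dist, dims) {
  d <- dist[idx]
  if (all(is.na(d))) {
    cand <- idx
  } else {
    cand <- idx[!is.na(d) & d == max(d, na.rm = TRUE)]
  }
  co <- arrayInd(cand, dims)
  co[order(co[, 1], co[, 2], co[, 3])[1], ]
}

#' Interior point of a domain
#'
#' The voxel of the domain at maximal city-block distance from any
#' differently-valued voxel (the most "inside" voxel), ties broken by
#' lexicographic `(x, y, z)` order. This is the point recorded for the domain
#' in the spatial SBML document.
#'
#' @param geom a `LabeledGeometry`.
#' @param domain a domain id (e.g. `"Nuc0"`) or one row of
#'   `label_domains(geom)$domains`.
#' @param domains optional precomputed [label_domains()] result.
#' @return Integer `(x, y, z)`, 0-based voxel indices.
#' @export
interior_point <- function(geom, domain, domains = label_domains(geom)) {
  if (is.character(domain)) {
    row <- domains$domains[domains$domains$id == domain, ]
    if (nrow(row) != 1L) stop_logic(sprintf("unknown or empty domain '%s'", domain))
    lab <- which(domains$domains$id == domain)
  } else {
    row <- domain
    lab <- which(domains$domains$id == row$id)
  }
  idx <- which(domains$label_grid == lab)
  if (!length(idx)) stop_logic(sprintf("domain '%s' is empty", row$id))
  dist <- .value_distance(geom$grid, row$sampled_value)
  .farthest_voxel(idx, dist, dim(geom$grid)) - 1L
}
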