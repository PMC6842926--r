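#' Fill enclosed holes in a binary mask
#'
#' Every background component that is not connected to the image border
#' (6-connected background flood fill) is set to foreground. Foreground
#' voxels are never removed, and the operation is idempotent.
#'
#' @param mask a binary [image_stack()].
#' @return The hole-filled binary `ImageStack`.
#' @examples
#' ring <- array(255L, c(5, 5, 1)); ring[3, 3, 1] <- 0L
#' s <- fill_holes(image_stack(ring))
#' s$voxels[3, 3, 1]
#' @export
fill_holes <- function(mask) {
  assert_binary(mask, "mask")
  bg <- !fg(mask)
  enclosed <- bg & !.border_reachable(bg)
  mask$voxels[enclosed] <- 255L
  mask
}

#' Fill the gap between two nested segmented regions
#'
#' When segmentation leaves a background shell between an inner region (e.g.
#' nucleus) and the outer region meant to enclose it (e.g. cytosol), the
#' enclosed background — background not reachable from the image border after
#' overlaying both masks — is assigned to the *outer* mask, preserving the
#' inner component's segmented boundary. Gapless input is returned unchanged.
#'
#' @param outer,inner binary [image_stack()]s with identical extents.
#' @return A list with elements `outer` (gap-filled) and `inner` (unchanged).
#' @export
fill_gap <- function(outer, inner) {
  assert_binary(outer, "outer"); assert_binary(inner, "inner")
  if (!same_extents(outer, inner))
    stop_input("'outer' and 'inner' must have identical extents")
  bg <- !(fg(outer) | fg(inner))
  enclosed <- bg & !.border_reachable(bg)
  outer$voxels[enclosed] <- 255L
  list(outer = outer, inner = inner)
}

#' Interpolate z-slices to remove voxel anisotropy
#'
#' Confocal z-stacks are typically undersampled along z (`dz > dx`). This
#' replicates each slice by the nearest-neighbour rule at integer factor
#' `k = round(dz/dx)`: output slice `j` is a copy of the input slice nearest
#' to `(j + 0.5)/k - 0.5` (0-based), the z-spacing becomes `dz/k`, and no new
#' voxel values are introduced. Isotropic input (`k = 1`) is returned
#' unchanged.
#'
#' @param stack a binary or labeled [image_stack()] with `dx == dy`.
#' @return The interpolated `ImageStack` with z-extent multiplied by `k`.
#' @export
interpolate_z <- function(stack) {
  assert_stack(stack)
  sp <- stack$spacing
  if (abs(sp[1] - sp[2]) > 1e-9 * max(sp[1], sp[2]))
    stop_input("unsupported anisotropy: dx != dy (only z-axis undersampling is handled)")
  k <- as.integer(round(sp[3] / sp[1]))
  if (k <= 1L) return(stack)
  nz <- dim(stack$voxels)[3]
  # 0-based source slice for each of the k*nz output slices
  j <- seq_len(k * nz) - 1L
  src <- pmin(nz - 1L, pmax(0L, as.integer(round((j + 0.5) / k - 0.5)))) + 1L
  stack$voxels <- stack$voxels[, , src, drop = FALSE]
  stack$spacing <- c(sp[1], sp[2], sp[3] / k)
  stack
}

#' Make overlapping masks disjoint (innermost wins)
#'
#' Every voxel claimed by two or more masks is kept only in the innermost
#' (deepest) claiming mask, carving inner regions out of outer ones, so the
#' merged geometry assigns each voxel a single domainType. The union of the
#' masks is preserved exactly.
#'
#' @param masks named list of binary [image_stack()]s with identical extents.
#' @param order character vector of mask names from outermost to innermost
#'   (without the extracellular background).
#' @return Named list of pairwise-disjoint binary `ImageStack`s, in `order`.
#' @export
resolve_overlap <- function(masks, order = names(masks)) {
  if (!length(masks)) return(masks)
  if (is.null(names(masks)) || !setequal(order, names(masks)))
    stop_input("'masks' must be a named list and 'order' a permutation of its names")
  for (nm in order) assert_binary(masks[[nm]], nm)
  dims <- dim(masks[[order[1]]]$voxels)
  for (nm in order) {
    if (!identical(dim(masks[[nm]]$voxels), dims))
      stop_input("all masks must have identical extents")
  }
  claim <- array(0L, dims)
  for (i in seq_along(order)) claim[fg(masks[[order[i]]])] <- i
  out <- list()
  for (i in seq_along(order)) {
    nm <- order[i]
    m <- masks[[nm]]
    m$voxels <- array(ifelse(claim == i, 255L, 0L), dims)
    if (!any(m$voxels != 0L) && any(fg(masks[[nm]])))
      warning("mask '", nm, "' is empty after overlap resolution ",
              "(fully covered by deeper masks)", call. = FALSE)
    out[[nm]] <- m
  }
  out
}
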