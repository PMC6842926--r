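# Deterministic synthetic-mask generators. Spheres are used because
# containment, adjacency and counts are analytically checkable; no
# randomness anywhere, so identical parameters give bit-identical masks.

.sphere_mask <- function(extents, center, radius, spacing, name) {
  if (radius <= 0)
    return(image_stack(array(0L, extents), spacing = spacing, name = name))
  co <- arrayInd(seq_len(prod(extents)), extents)
  d2 <- (co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 + (co[, 3] - center[3])^2
  v <- array(ifelse(d2 <= radius^2, 255L, 0L), extents)
  image_stack(v, spacing = spacing, name = name)
}

#' Nested-spheres fixture: a nucleus inside a cytosol
#'
#' Two binary masks on the same grid: a cytosol sphere of radius
#' `radii[1]` and a nucleus sphere of radius `radii[2]` around the same
#' centre, the standard two-component input (extracellular background is
#' implicit).
#'
#' @param extents integer length-3 grid size `(nx, ny, nz)`.
#' @param center sphere centre in 1-based voxel coordinates; defaults to the
#'   grid centre.
#' @param radii strictly decreasing `(r_outer, r_inner)` in voxels; the
#'   spheres must fit inside the grid.
#' @param spacing voxel spacing passed to the masks.
#' @return Named list of binary `ImageStack`s: `Cyt`, `Nuc`.
#' @export
nested_spheres <- function(extents = c(32, 32, 32), center = (extents + 1) / 2,
                           radii = c(12, 6), spacing = c(1, 1, 1)) {
  extents <- as.integer(extents)
  if (length(radii) != 2L || radii[1] <= radii[2] || radii[2] < 0)
    stop_input("'radii' must be strictly decreasing (r_outer > r_inner >= 0)")
  if (any(center - radii[1] < 0.5) || any(center + radii[1] > extents + 0.5))
    stop_input("outer sphere does not fit inside the grid")
  list(Cyt = .sphere_mask(extents, center, radii[1], spacing, "Cyt"),
       Nuc = .sphere_mask(extents, center, radii[2], spacing, "Nuc"))
}

#' Gapped-spheres fixture: a background gap between nucleus and cytosol
#'
#' Emulates a segmentation artifact: the cytosol is a shell starting
#' `gap_width` voxels outside the nucleus surface, leaving an enclosed
#' background gap between the two regions that [fill_gap()] must close.
#' `gap_width = 0` reproduces the [nested_spheres()] masks.
#'
#' @param extents grid size.
#' @param center sphere centre (1-based voxel coordinates).
#' @param radii `(r_outer, r_inner)` as in [nested_spheres()].
#' @param gap_width gap thickness in voxels (>= 0).
#' @param spacing voxel spacing.
#' @return Named list of binary `ImageStack`s: `Cyt` (shell), `Nuc`.
#' @export
gapped_spheres <- function(extents = c(32, 32, 32), center = (extents + 1) / 2,
                           radii = c(12, 6), gap_width = 2, spacing = c(1, 1, 1)) {
  if (gap_width < 0) stop_input("'gap_width' must be >= 0")
  if (radii[2] + gap_width >= radii[1])
    stop_input("gap does not fit: need r_inner + gap_width < r_outer")
  fx <- nested_spheres(extents, center, radii, spacing)
  if (gap_width > 0) {
    hole <- .sphere_mask(as.integer(extents), center, radii[2] + gap_width,
                         spacing, "hole")
    fx$Cyt$voxels[fg(hole)] <- 0L
  }
  fx
}

#' Decimate z-slices to simulate anisotropic acquisition
#'
#' Keeps every `k`-th z-slice (starting at the first) and multiplies the
#' z-spacing by `k`, emulating the low z-resolution of a confocal stack;
#' [interpolate_z()] inverts the spacing change by nearest-neighbour
#' replication.
#'
#' @param mask an [image_stack()].
#' @param keep_every_k integer decimation factor `k >= 2`, smaller than the
#'   z-extent.
#' @return The decimated `ImageStack` with spacing `(dx, dy, k * dz)`.
#' @export
anisotropic_stack <- function(mask, keep_every_k) {
  assert_stack(mask)
  k <- as.integer(keep_every_k)
  if (k < 2L) stop_input("'keep_every_k' must be >= 2")
  nz <- dim(mask$voxels)[3]
  if (k >= nz) stop_input(sprintf("'keep_every_k' (%d) must be smaller than the z-extent (%d)", k, nz))
  keep <- seq(1L, nz, by = k)
  mask$voxels <- mask$voxels[, , keep, drop = FALSE]
  mask$spacing[3] <- mask$spacing[3] * k
  mask
}

#' Multi-nucleus fixture: several nuclei inside one cytosol
#'
#' One `Nuc` mask holding several disjoint spheres inside a single `Cyt`
#' sphere, exercising multiple domains (and membrane domains) of one
#' domainType.
#'
#' @param extents grid size.
#' @param centers list of nucleus centres (1-based voxel coordinates).
#' @param radii `(r_cyt, r_nuc)`: cytosol radius and common nucleus radius.
#' @param cyt_center cytosol centre; defaults to the grid centre.
#' @param spacing voxel spacing.
#' @return Named list of binary `ImageStack`s: `Cyt`, `Nuc`.
#' @export
multi_nucleus <- function(extents = c(32, 32, 32), centers,
                          radii = c(13, 3), cyt_center = (extents + 1) / 2,
                          spacing = c(1, 1, 1)) {
  extents <- as.integer(extents)
  cyt <- .sphere_mask(extents, cyt_center, radii[1], spacing, "Cyt")
  nuc <- image_stack(array(0L, extents), spacing = spacing, name = "Nuc")
  for (i in seq_along(centers)) {
    ctr <- centers[[i]]
    d <- sqrt(sum((ctr - cyt_center)^2))
    if (d + radii[2] >= radii[1])
      stop_input(sprintf("nucleus %d does not fit strictly inside the cytosol", i))
    s <- .sphere_mask(extents, ctr, radii[2], spacing, "Nuc")
    if (any(fg(s) & fg(nuc)))
      stop_input(sprintf("nucleus %d overlaps an earlier nucleus", i))
    nuc$voxels[fg(s)] <- 255L
  }
  list(Cyt = cyt, Nuc = nuc)
}
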