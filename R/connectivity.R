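# Voxel-grid connectivity primitives shared by preprocessing, domain
# labeling and interior-point selection. All work on linear (1-based)
# indices into a 3D array; frontiers are expanded vectorised, one BFS
# layer at a time.

.offsets <- function(connectivity) {
  if (connectivity == 6L) {
    matrix(c( 1L, 0L, 0L, -1L, 0L, 0L,
              0L, 1L, 0L,  0L,-1L, 0L,
              0L, 0L, 1L,  0L, 0L,-1L), ncol = 3, byrow = TRUE)
  } else if (connectivity == 26L) {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    storage.mode(g) <- "integer"
    unname(g[rowSums(abs(g)) > 0L, , drop = FALSE])
  } else stop_logic("connectivity must be 6 or 26")
}

# in-bounds neighbours (linear indices, deduplicated) of a frontier
.neighbours <- function(idx, dims, off) {
  co <- arrayInd(idx, dims)
  n <- nrow(co); m <- nrow(off)
  nb <- co[rep(seq_len(n), each = m), , drop = FALSE] +
        off[rep.int(seq_len(m), n), , drop = FALSE]
  ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
        nb[, 2] >= 1L & nb[, 2] <= dims[2] &
        nb[, 3] >= 1L & nb[, 3] <= dims[3]
  nb <- nb[ok, , drop = FALSE]
  unique.default((nb[, 3] - 1L) * (dims[1] * dims[2]) +
                 (nb[, 2] - 1L) * dims[1] + nb[, 1])
}

# label connected components of a logical array; returns integer array,
# 0 = not in mask, components numbered 1..k in discovery order
.label_components <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  off <- .offsets(connectivity)
  labels <- array(0L, dims)
  lab <- 0L
  for (s in which(mask)) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    labels[s] <- lab
    frontier <- s
    while (length(frontier)) {
      nb <- .neighbours(frontier, dims, off)
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- lab
      frontier <- nb
    }
  }
  labels
}

# image-border voxels; faces are only counted along axes with extent > 1,
# so a single-slice (2D) stack keeps its x/y border without every voxel
# becoming border through the degenerate z axis
.border_indices <- function(dims) {
  a <- array(FALSE, dims)
  if (dims[1] > 1L) a[c(1L, dims[1]), , ] <- TRUE
  if (dims[2] > 1L) a[, c(1L, dims[2]), ] <- TRUE
  if (dims[3] > 1L) a[, , c(1L, dims[3])] <- TRUE
  if (!any(a)) a[] <- TRUE
  which(a)
}

# logical array: background voxels reachable from the image border through
# background, using 6-connectivity (complementary to 26-connected foreground)
.border_reachable <- function(bg, connectivity = 6L) {
  dims <- dim(bg)
  off <- .offsets(connectivity)
  reach <- array(FALSE, dims)
  frontier <- .border_indices(dims)
  frontier <- frontier[bg[frontier]]
  reach[frontier] <- TRUE
  while (length(frontier)) {
    nb <- .neighbours(frontier, dims, off)
    nb <- nb[bg[nb] & !reach[nb]]
    reach[nb] <- TRUE
    frontier <- nb
  }
  reach
}

# multi-source BFS distance (6-connectivity, i.e. city-block metric on an
# unobstructed grid) from the seed set; NA where unreachable/no seeds
.bfs_distance <- function(seeds, dims) {
  d <- array(NA_integer_, dims)
  if (!length(seeds)) return(d)
  off <- .offsets(6L)
  d[seeds] <- 0L
  frontier <- seeds
  step <- 0L
  while (length(frontier)) {
    step <- step + 1L
    nb <- .neighbours(frontier, dims, off)
    nb <- nb[is.na(d[nb])]
    d[nb] <- step
    frontier <- nb
  }
  d
}
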