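# Independent oracles for labeling, adjacency and hole filling, built on
# igraph components and brute-force pair scans rather than the package's
# BFS machinery. Only usable on small grids.

.oracle_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  g
}

# voxel adjacency edge list among the voxels `idx` of a grid; brute-force
# all-pairs distances on small inputs, an offset join on large fixtures
# (dense pairwise distances on a 26^3 grid would need gigabytes)
.oracle_edges <- function(idx, dims, connectivity) {
  if (length(idx) < 2) return(matrix(integer(0), ncol = 2))
  if (length(idx) <= 400) {
    co <- arrayInd(idx, dims)
    d <- as.matrix(stats::dist(co, method = if (connectivity == 6) "manhattan" else "maximum"))
    w <- which(upper.tri(d) & d == 1, arr.ind = TRUE)
    return(cbind(idx[w[, 1]], idx[w[, 2]]))
  }
  off <- .oracle_offsets(connectivity)
  co <- arrayInd(idx, dims)
  ed <- list()
  for (r in seq_len(nrow(off))) {
    nb <- sweep(co, 2, off[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- (nb[ok, 3] - 1) * dims[1] * dims[2] + (nb[ok, 2] - 1) * dims[1] + nb[ok, 1]
    m <- match(lin, idx)
    hit <- !is.na(m)
    src <- idx[ok][hit]; dst <- idx[m[hit]]
    keep <- src < dst
    ed[[r]] <- cbind(src[keep], dst[keep])
  }
  unique(do.call(rbind, ed))
}

# connected components of the voxels with grid == value, via igraph
oracle_components <- function(grid, value, connectivity = 26) {
  idx <- which(grid == value)
  if (!length(idx)) return(list())
  ed <- .oracle_edges(idx, dim(grid), connectivity)
  g <- igraph::graph_from_edgelist(matrix(match(as.vector(ed), idx), ncol = 2),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  mem <- igraph::components(g)$membership
  unname(split(idx, mem))
}

# all-pairs face-adjacency between labels of a fully labeled grid:
# returns data frame label1 < label2 with shared-face counts
oracle_adjacency <- function(label_grid) {
  dims <- dim(label_grid)
  idx <- seq_len(prod(dims))
  co <- arrayInd(idx, dims)
  d <- as.matrix(stats::dist(co, method = "manhattan"))
  w <- which(upper.tri(d) & d == 1, arr.ind = TRUE)
  l1 <- label_grid[idx[w[, 1]]]; l2 <- label_grid[idx[w[, 2]]]
  keep <- l1 != l2
  if (!any(keep)) return(data.frame(a = integer(), b = integer(), faces = integer()))
  a <- pmin(l1[keep], l2[keep]); b <- pmax(l1[keep], l2[keep])
  agg <- stats::aggregate(list(faces = rep(1L, length(a))),
                          by = list(a = a, b = b), FUN = sum)
  agg[order(agg$a, agg$b), ]
}

# hole filling oracle: background components (6-connected) that touch no
# border voxel are holes
oracle_fill_holes <- function(vox) {
  dims <- dim(vox)
  comps <- oracle_components(vox, 0L, connectivity = 6)
  co <- arrayInd(seq_len(prod(dims)), dims)
  # the image border of a degenerate (extent-1) axis does not count: a 2D
  # slice keeps its x/y border only
  onb <- rep(FALSE, prod(dims))
  for (ax in 1:3) if (dims[ax] > 1) onb <- onb | co[, ax] == 1 | co[, ax] == dims[ax]
  border <- which(onb)
  for (cp in comps) if (!any(cp %in% border)) vox[cp] <- 255L
  vox
}

random_label_grid <- function(dims, values = c(0L, 85L, 170L),
                              prob = NULL) {
  array(sample(values, prod(dims), replace = TRUE, prob = prob), dims)
}

# full pipeline convenience for fixtures
pipeline_model <- function(fx, ...) convert_images(fx, ...)

# foreground of a mask (mirror of the package-internal helper)
fg <- function(s) s$voxels != 0L
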