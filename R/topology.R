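#' Detect face adjacency between domains
#'
#' Two domains are adjacent iff some voxel of one shares a face (6-
#' neighbourhood) with a voxel of the other; diagonal-only contact has no
#' surface and does not count. The number of shared voxel faces is recorded
#' per edge, as a proxy for membrane contact area.
#'
#' @param geom a `LabeledGeometry`.
#' @param domains the matching [label_domains()] `DomainSet`.
#' @return An object of class `AdjacencyGraph`: list with `nodes` (the domain
#'   data frame), `edges` (data frame `domain1`, `domain2`, `faces`; pairs
#'   ordered so `domain1` is the deeper side when membranes are created), and
#'   empty membrane slots filled in by [create_membranes()].
#' @export
detect_adjacency <- function(geom, domains = label_domains(geom)) {
  if (!inherits(domains, "DomainSet")) stop_input("'domains' must be a DomainSet")
  lab <- domains$label_grid
  dims <- dim(lab)
  pairs <- list()
  if (dims[1] > 1L)
    pairs[[1]] <- cbind(as.vector(lab[-dims[1], , , drop = FALSE]),
                        as.vector(lab[-1L, , , drop = FALSE]))
  if (dims[2] > 1L)
    pairs[[2]] <- cbind(as.vector(lab[, -dims[2], , drop = FALSE]),
                        as.vector(lab[, -1L, , drop = FALSE]))
  if (dims[3] > 1L)
    pairs[[3]] <- cbind(as.vector(lab[, , -dims[3], drop = FALSE]),
                        as.vector(lab[, , -1L, drop = FALSE]))
  p <- do.call(rbind, pairs)
  edges <- data.frame(domain1 = character(), domain2 = character(),
                      faces = integer(), stringsAsFactors = FALSE)
  if (!is.null(p) && nrow(p)) {
    p <- p[p[, 1] != p[, 2] & p[, 1] > 0L & p[, 2] > 0L, , drop = FALSE]
    if (nrow(p)) {
      a <- pmin(p[, 1], p[, 2]); b <- pmax(p[, 1], p[, 2])
      key <- paste(a, b)
      tab <- table(key)
      ab <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
      ids <- domains$domains$id
      edges <- data.frame(domain1 = ids[as.integer(ab[, 1])],
                          domain2 = ids[as.integer(ab[, 2])],
                          faces = as.integer(tab), stringsAsFactors = FALSE)
      edges <- edges[order(edges$domain1, edges$domain2), ]
      rownames(edges) <- NULL
    }
  }
  structure(list(nodes = domains$domains, edges = edges,
                 membrane_types = NULL, membranes = NULL,
                 adjacent_domains = NULL),
            class = "AdjacencyGraph")
}

#' @export
print.AdjacencyGraph <- function(x, ...) {
  cat("AdjacencyGraph:", nrow(x$nodes), "domains,", nrow(x$edges), "edges")
  if (!is.null(x$membranes)) cat(",", nrow(x$membranes), "membranes")
  cat("\n")
  if (nrow(x$edges)) print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Create zero-thickness membranes between adjacent domains
#'
#' For each adjacency between two volume domains, one membrane domainType
#' (dimension 2, no sampled value, no voxels) is created per ordered pair of
#' volume domainTypes, plus one membrane domain per adjacent domain pair and
#' two `adjacentDomains` records linking the membrane to its inner and outer
#' neighbour. The two canonical cases keep their biological names: `PM`
#' (plasma membrane, cytosol|extracellular) and `NM` (nuclear membrane,
#' nucleus|cytosol); all other pairs are named
#' `"<inner>_<outer>_membrane"`.
#'
#' @param graph an [detect_adjacency()] `AdjacencyGraph`.
#' @param depth_order depth order from [containment_hierarchy()] (or the
#'   `depth_order` of the geometry).
#' @return The graph with `membrane_types` (data frame `name`, `inner_type`,
#'   `outer_type`), `membranes` (data frame `id`, `membrane_type`, `inner`,
#'   `outer`) and `adjacent_domains` (data frame `id`, `domain1` = membrane,
#'   `domain2` = volume domain) filled in.
#' @export
create_membranes <- function(graph, depth_order) {
  if (!inherits(graph, "AdjacencyGraph")) stop_input("'graph' must be an AdjacencyGraph")
  type_of <- stats::setNames(graph$nodes$domain_type, graph$nodes$id)
  pos <- stats::setNames(seq_along(depth_order) - 1L, depth_order)
  e <- graph$edges
  mem <- list(); mtypes <- list()
  if (nrow(e)) {
    t1 <- type_of[e$domain1]; t2 <- type_of[e$domain2]
    deeper1 <- pos[t1] >= pos[t2]
    inner_d <- ifelse(deeper1, e$domain1, e$domain2)
    outer_d <- ifelse(deeper1, e$domain2, e$domain1)
    inner_t <- unname(type_of[inner_d]); outer_t <- unname(type_of[outer_d])
    mname <- ifelse(inner_t == "Nuc" & outer_t == "Cyt", "NM",
             ifelse(inner_t == "Cyt" & outer_t == "EC", "PM",
                    paste0(inner_t, "_", outer_t, "_membrane")))
    ord <- order(mname, inner_d, outer_d)
    ids <- character(length(ord)); seen <- integer(0)
    cnt <- new.env(parent = emptyenv())
    for (i in ord) {
      k <- if (is.null(cnt[[mname[i]]])) 0L else cnt[[mname[i]]]
      ids[i] <- paste0(mname[i], k)
      cnt[[mname[i]]] <- k + 1L
    }
    mtypes <- unique(data.frame(name = mname, inner_type = inner_t,
                                outer_type = outer_t, stringsAsFactors = FALSE))
    mtypes <- mtypes[order(mtypes$name), ]
    rownames(mtypes) <- NULL
    mem <- data.frame(id = ids, membrane_type = mname,
                      inner = inner_d, outer = outer_d, stringsAsFactors = FALSE)
    mem <- mem[order(mem$id), ]
    rownames(mem) <- NULL
    adj <- data.frame(
      id = c(paste0("adj_", mem$id, "_", mem$inner),
             paste0("adj_", mem$id, "_", mem$outer)),
      domain1 = c(mem$id, mem$id),
      domain2 = c(mem$inner, mem$outer), stringsAsFactors = FALSE)
    adj <- adj[order(adj$id), ]
    rownames(adj) <- NULL
    graph$membrane_types <- mtypes
    graph$membranes <- mem
    graph$adjacent_domains <- adj
  } else {
    graph$membrane_types <- data.frame(name = character(), inner_type = character(),
                                       outer_type = character(), stringsAsFactors = FALSE)
    graph$membranes <- data.frame(id = character(), membrane_type = character(),
                                  inner = character(), outer = character(),
                                  stringsAsFactors = FALSE)
    graph$adjacent_domains <- data.frame(id = character(), domain1 = character(),
                                         domain2 = character(), stringsAsFactors = FALSE)
  }
  graph
}

#' Check the biological consistency of the adjacency structure
#'
#' An organelle should only touch the compartment directly containing it: an
#' adjacency whose two domainTypes differ by anything other than one level of
#' containment depth (e.g. a nucleus touching the extracellular matrix) is
#' biologically impossible and reported as a warning. Warnings never block
#' export.
#'
#' @param graph an `AdjacencyGraph`.
#' @param hierarchy result of [containment_hierarchy()]; its `"depths"`
#'   attribute is used when present, else list position.
#' @return Character vector of warning messages (empty when consistent).
#' @export
check_biology <- function(graph, hierarchy) {
  if (!inherits(graph, "AdjacencyGraph")) stop_input("'graph' must be an AdjacencyGraph")
  depths <- attr(hierarchy, "depths")
  if (is.null(depths)) depths <- seq_along(hierarchy) - 1L
  depth <- stats::setNames(depths, as.character(hierarchy))
  type_of <- stats::setNames(graph$nodes$domain_type, graph$nodes$id)
  e <- graph$edges
  out <- character(0)
  for (i in seq_len(nrow(e))) {
    t1 <- type_of[[e$domain1[i]]]; t2 <- type_of[[e$domain2[i]]]
    dd <- abs(depth[[t1]] - depth[[t2]])
    if (dd != 1L)
      out <- c(out, sprintf("%s adjacent to %s (%s/%s): containment depths differ by %d, expected 1",
                            t1, t2, e$domain1[i], e$domain2[i], dd))
  }
  unique(out)
}

#' Export the adjacency graph in DOT format
#'
#' Writes the domain/adjacency structure as a Graphviz DOT text file: one
#' node per domain (membranes boxed), one edge per adjacency record,
#' mirroring the inclusion-property view of the model.
#'
#' @param graph an `AdjacencyGraph` (membranes optional).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(graph, path) {
  if (!inherits(graph, "AdjacencyGraph")) stop_input("'graph' must be an AdjacencyGraph")
  lines <- c("graph adjacency {", "  node [shape=ellipse];")
  for (id in graph$nodes$id) lines <- c(lines, sprintf("  \"%s\";", id))
  if (!is.null(graph$membranes) && nrow(graph$membranes))
    lines <- c(lines, sprintf("  \"%s\" [shape=box];", graph$membranes$id))
  if (!is.null(graph$adjacent_domains) && nrow(graph$adjacent_domains)) {
    lines <- c(lines, sprintf("  \"%s\" -- \"%s\";",
                              graph$adjacent_domains$domain1,
                              graph$adjacent_domains$domain2))
  } else if (nrow(graph$edges)) {
    lines <- c(lines, sprintf("  \"%s\" -- \"%s\";",
                              graph$edges$domain1, graph$edges$domain2))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
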