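nested_graph <- function(extents = c(20, 20, 20), radii = c(7, 3)) {
  fx <- nested_spheres(extents, radii = radii)
  geom <- merge_masks(resolve_overlap(fx, order = c("Cyt", "Nuc")),
                      order = containment_hierarchy(fx))
  doms <- label_domains(geom)
  list(geom = geom, doms = doms, graph = detect_adjacency(geom, doms))
}

test_that("detect_adjacency finds exactly the face-sharing domain pairs", {
  g <- nested_graph()
  e <- g$graph$edges
  expect_identical(nrow(e), 2L)
  expect_setequal(paste(e$domain1, e$domain2), c("EC0 Cyt0", "Cyt0 Nuc0"))
  expect_true(all(e$faces > 0L))

  # two disjoint nuclei: no Nuc0-Nuc1 edge
  fx <- multi_nucleus(c(32, 32, 32), centers = list(c(11, 16, 16), c(22, 16, 16)),
                      radii = c(13, 3))
  geom <- merge_masks(resolve_overlap(fx, order = c("Cyt", "Nuc")),
                      order = c("EC", "Cyt", "Nuc"))
  doms <- label_domains(geom)
  e2 <- detect_adjacency(geom, doms)$edges
  expect_setequal(paste(e2$domain1, e2$domain2),
                  c("EC0 Cyt0", "Cyt0 Nuc0", "Cyt0 Nuc1"))

  # minimal case: 2x1x1 grid, one shared face
  grid <- array(c(85L, 170L), c(2, 1, 1))
  geom3 <- structure(list(grid = grid, value_map = c(EC = 0L, Cyt = 85L, Nuc = 170L),
                          spacing = c(1, 1, 1), depth_order = c("EC", "Cyt", "Nuc")),
                     class = "LabeledGeometry")
  e3 <- detect_adjacency(geom3)$edges
  expect_identical(nrow(e3), 1L)
  expect_identical(e3$faces, 1L)
})

test_that("diagonal-only contact is not adjacency", {
  grid <- array(0L, c(2, 2, 1))
  grid[1, 1, 1] <- 85L; grid[2, 2, 1] <- 170L
  geom <- structure(list(grid = grid, value_map = c(EC = 0L, Cyt = 85L, Nuc = 170L),
                         spacing = c(1, 1, 1), depth_order = c("EC", "Cyt", "Nuc")),
                    class = "LabeledGeometry")
  e <- detect_adjacency(geom)$edges
  expect_false(any((e$domain1 == "Cyt0" & e$domain2 == "Nuc0") |
                   (e$domain1 == "Nuc0" & e$domain2 == "Cyt0")))
})

test_that("adjacency matches the all-pairs oracle on random grids", {
  set.seed(404)
  for (i in 1:40) {
    dims <- sample(2:5, 3, replace = TRUE)
    grid <- random_label_grid(dims)
    geom <- structure(list(grid = grid, value_map = c(EC = 0L, Cyt = 85L, Nuc = 170L),
                           spacing = c(1, 1, 1), depth_order = c("EC", "Cyt", "Nuc")),
                      class = "LabeledGeometry")
    doms <- label_domains(geom)
    mine <- detect_adjacency(geom, doms)$edges
    orac <- oracle_adjacency(doms$label_grid)
    ids <- doms$domains$id
    orac_ids <- data.frame(domain1 = ids[orac$a], domain2 = ids[orac$b],
                           faces = orac$faces)
    canon <- function(df) {
      a <- pmin(df$domain1, df$domain2); b <- pmax(df$domain1, df$domain2)
      o <- order(a, b)
      data.frame(a = a[o], b = b[o], faces = df$faces[o])
    }
    expect_identical(canon(mine), canon(orac_ids))
  }
})

test_that("adjacency is invariant under swapping two sampled values", {
  set.seed(405)
  grid <- random_label_grid(c(4, 4, 4))
  swap <- grid
  swap[grid == 85L] <- 170L; swap[grid == 170L] <- 85L
  mk <- function(g, vm) structure(
    list(grid = g, value_map = vm, spacing = c(1, 1, 1),
         depth_order = names(vm)), class = "LabeledGeometry")
  geom1 <- mk(grid, c(EC = 0L, Cyt = 85L, Nuc = 170L))
  geom2 <- mk(swap, c(EC = 0L, Nuc = 85L, Cyt = 170L))
  d1 <- label_domains(geom1); d2 <- label_domains(geom2)
  # the regions are identical point sets under the swap; identify each
  # domain by the minimum linear index of its region and compare edges
  region_key <- function(doms) {
    ids <- doms$domains$id
    vapply(seq_along(ids), function(i) min(which(doms$label_grid == i)), integer(1)) |>
      stats::setNames(ids)
  }
  k1 <- region_key(d1); k2 <- region_key(d2)
  canon <- function(e, k) {
    a <- pmin(k[e$domain1], k[e$domain2]); b <- pmax(k[e$domain1], k[e$domain2])
    o <- order(a, b); data.frame(a = unname(a[o]), b = unname(b[o]), faces = e$faces[o])
  }
  expect_identical(canon(detect_adjacency(geom1, d1)$edges, k1),
                   canon(detect_adjacency(geom2, d2)$edges, k2))
})

test_that("create_membranes yields PM/NM for the canonical pairs, one membrane per edge", {
  g <- nested_graph()
  graph <- create_membranes(g$graph, g$geom$depth_order)
  expect_setequal(graph$membrane_types$name, c("PM", "NM"))
  expect_identical(nrow(graph$membranes), nrow(graph$edges))
  expect_identical(graph$membranes$inner[graph$membranes$membrane_type == "NM"], "Nuc0")
  expect_identical(graph$membranes$outer[graph$membranes$membrane_type == "NM"], "Cyt0")
  expect_identical(graph$membranes$inner[graph$membranes$membrane_type == "PM"], "Cyt0")
  expect_identical(graph$membranes$outer[graph$membranes$membrane_type == "PM"], "EC0")
  # two ordered adjacentDomains records per membrane, membrane listed first
  expect_identical(nrow(graph$adjacent_domains), 2L * nrow(graph$membranes))
  expect_true(all(graph$adjacent_domains$domain1 %in% graph$membranes$id))
})

test_that("a nested chain of n volume types yields exactly n-1 membranes", {
  dims <- c(26, 26, 26)
  radii <- c(11, 9, 7, 5, 3)
  masks <- list()
  for (i in seq_along(radii))
    masks[[paste0("L", i)]] <- imgsbml:::.sphere_mask(dims, c(13, 13, 13),
                                                      radii[i], c(1, 1, 1),
                                                      paste0("L", i))
  h <- containment_hierarchy(masks)
  carved <- resolve_overlap(masks, order = setdiff(h, "EC"))
  geom <- merge_masks(carved, order = h)
  graph <- create_membranes(detect_adjacency(geom), h)
  expect_identical(nrow(graph$membranes), length(radii))  # EC chain included: 6 types, 5 interfaces
  expect_identical(nrow(graph$membranes), nrow(graph$edges))
  # systematic names for non-canonical pairs
  expect_true(all(grepl("_membrane[0-9]+$", graph$membranes$id)))
})

test_that("one membrane domain per adjacent domain pair under a shared membrane type", {
  fx <- multi_nucleus(c(32, 32, 32), centers = list(c(11, 16, 16), c(22, 16, 16)),
                      radii = c(13, 3))
  m <- convert_images(fx)
  nm <- m$graph$membranes[m$graph$membranes$membrane_type == "NM", ]
  expect_identical(nrow(nm), 2L)
  expect_setequal(nm$id, c("NM0", "NM1"))
  expect_identical(sum(m$domain_types$name == "NM"), 1L)
})

test_that("check_biology flags only adjacencies that skip containment levels", {
  g <- nested_graph()
  h <- containment_hierarchy(nested_spheres(c(20, 20, 20), radii = c(7, 3)))
  expect_identical(check_biology(g$graph, h), character(0))

  # nucleus protruding through the cytosol touches EC
  fx <- nested_spheres(c(24, 24, 24), radii = c(8, 4))
  fx$Nuc$voxels[12, 12, 1:24] <- 255L   # spike through everything
  suppressWarnings({
    carved <- resolve_overlap(fx, order = c("Cyt", "Nuc"))
    geom <- merge_masks(carved, order = c("EC", "Cyt", "Nuc"))
    graph <- detect_adjacency(geom)
  })
  hier <- structure(c("EC", "Cyt", "Nuc"), depths = 0:2)
  warns <- check_biology(graph, hier)
  expect_true(any(grepl("Nuc adjacent to EC|EC adjacent to Nuc", warns)))

  # EC-only geometry: no edges, no warnings
  geom0 <- merge_masks(list(), order = "EC")
  graph0 <- detect_adjacency(geom0)
  expect_identical(check_biology(graph0, structure("EC", depths = 0L)), character(0))
})

test_that("write_dot exports nodes and adjacency edges", {
  g <- nested_graph()
  graph <- create_membranes(g$graph, g$geom$depth_order)
  f <- withr::local_tempfile(fileext = ".dot")
  write_dot(graph, f)
  txt <- readLines(f)
  expect_true(any(grepl("graph adjacency", txt)))
  for (id in c("EC0", "Cyt0", "Nuc0")) expect_true(any(grepl(id, txt, fixed = TRUE)))
  expect_true(any(grepl("--", txt, fixed = TRUE)))
})
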