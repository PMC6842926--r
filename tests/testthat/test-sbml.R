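nested_model <- function(extents = c(20, 20, 20), radii = c(7, 3)) {
  convert_images(nested_spheres(extents, radii = radii))
}

test_that("build_model carries the Fig-style structure: 5 domainTypes, sampled values on volumes only", {
  m <- nested_model()
  expect_setequal(m$domain_types$name, c("EC", "Cyt", "Nuc", "PM", "NM"))
  vols <- m$domain_types[m$domain_types$dimension == 3L, ]
  mems <- m$domain_types[m$domain_types$dimension == 2L, ]
  expect_setequal(vols$name, c("EC", "Cyt", "Nuc"))
  expect_identical(sort(vols$sampled_value), c(0L, 85L, 170L))
  expect_true(all(is.na(mems$sampled_value)))
  expect_identical(nrow(m$domains), 5L)
  expect_identical(nrow(m$adjacent_domains), 4L)
  # every domainType maps to exactly one compartment with the right dimension
  expect_identical(sort(m$compartments$domain_type), sort(m$domain_types$name))
  expect_identical(
    m$compartments$spatial_dimensions[match(m$domain_types$name, m$compartments$domain_type)],
    m$domain_types$dimension)
  # volume compartment size = voxel_count * voxel volume
  cyt_n <- m$domains$voxel_count[m$domains$id == "Cyt0"]
  expect_equal(m$compartments$size[m$compartments$domain_type == "Cyt"], cyt_n * 1)
})

test_that("a hand-built 2x2x1 geometry serializes with the declared voxel order and bounds", {
  grid <- array(c(0L, 85L, 0L, 85L), c(2, 2, 1))
  geom <- structure(list(grid = grid, value_map = c(EC = 0L, Cyt = 85L),
                         spacing = c(2, 2, 2), depth_order = c("EC", "Cyt")),
                    class = "LabeledGeometry")
  doms <- label_domains(geom)
  graph <- create_membranes(detect_adjacency(geom, doms), geom$depth_order)
  m <- build_model(geom, doms, graph)
  f <- withr::local_tempfile(fileext = ".xml")
  export_sbml(m, f)
  doc <- xml2::read_xml(f)
  ns <- xml2::xml_ns(doc)
  sf <- xml2::xml_find_first(doc, ".//spatial:sampledField", ns)
  expect_identical(xml2::xml_text(sf), "0 85 0 85")
  expect_identical(xml2::xml_attr(sf, "numSamples1"), "2")
  xmax <- xml2::xml_find_first(
    doc, ".//spatial:coordinateComponent[@spatial:type='cartesianX']/spatial:boundaryMax", ns)
  expect_identical(xml2::xml_attr(xmax, "value"), "4")
})

test_that("EC-only geometry still builds and exports a minimal valid document", {
  geom <- merge_masks(list(), order = "EC")
  doms <- label_domains(geom)
  graph <- create_membranes(detect_adjacency(geom, doms), "EC")
  m <- build_model(geom, doms, graph)
  expect_identical(nrow(m$domain_types), 1L)
  expect_identical(nrow(m$domains), 1L)
  expect_identical(nrow(m$adjacent_domains), 0L)
  f <- withr::local_tempfile(fileext = ".xml")
  export_sbml(m, f)
  doc <- xml2::read_xml(f)
  expect_identical(length(xml2::xml_find_all(doc, ".//d1:compartment", xml2::xml_ns(doc))), 1L)
})

test_that("add_species enforces uniqueness and resolves compartments by name", {
  m <- nested_model()
  m <- add_species(m, "A", "Cyt", 1.0)
  expect_identical(nrow(m$species), 1L)
  expect_error(add_species(m, "A", "Cyt", 2.0), "duplicate",
               class = "imgsbml_input_error")
  expect_error(add_species(m, "B", "Golgi", 1.0), class = "imgsbml_input_error")
  # membrane compartments accept surface-bound species
  m <- add_species(m, "R", "PM", 0.5)
  expect_identical(m$species$compartment[m$species$id == "R"],
                   m$compartments$id[m$compartments$domain_type == "PM"])
})

test_that("add_spatial_parameter validates roles, targets and axes", {
  m <- add_species(nested_model(), "A", "Cyt", 1.0)
  m <- add_spatial_parameter(m, "D_A", 1e-12, role = "diffusion", species = "A")
  m <- add_spatial_parameter(m, "bc_A", 0, role = "boundary-condition",
                             species = "A", axis = "Xmax")
  m <- add_spatial_parameter(m, "k1", 0.5)
  expect_identical(m$parameters$role, c("diffusion", "boundary-condition", "none"))
  expect_error(add_spatial_parameter(m, "v_A", 1, role = "advection", species = "A"),
               "axis", class = "imgsbml_input_error")
  expect_error(add_spatial_parameter(m, "D_B", 1, role = "diffusion", species = "B"),
               class = "imgsbml_input_error")
})

test_that("add_reaction checks identifiers and stores normalized rate expressions", {
  m <- nested_model()
  m <- add_species(m, "A_cyt", "Cyt", 1.0)
  m <- add_species(m, "A_ec", "EC", 0.0)
  m <- add_spatial_parameter(m, "k1", 0.5)
  m <- add_reaction(m, "transport", reactants = "A_cyt", products = "A_ec",
                    rate_expression = "k1*A_cyt", membrane_local = TRUE,
                    compartment = "PM")
  expect_identical(m$reactions[[1]]$rate, "k1 * A_cyt")
  expect_true(m$reactions[[1]]$membrane_local)
  m <- add_reaction(m, "degrade", reactants = "A_cyt", products = character(),
                    rate_expression = "k1*A_cyt")
  expect_identical(length(m$reactions), 2L)
  err <- tryCatch(add_reaction(m, "bad", "A_cyt", character(), "k9*A_cyt"),
                  error = identity)
  expect_s3_class(err, "imgsbml_input_error")
  expect_match(conditionMessage(err), "k9")
})

test_that("export declares L3V1 with the spatial package required", {
  m <- nested_model(c(16, 16, 16), radii = c(6, 3))
  f <- withr::local_tempfile(fileext = ".xml")
  export_sbml(m, f)
  doc <- xml2::read_xml(f)
  root <- xml2::xml_root(doc)
  expect_identical(xml2::xml_attr(root, "level"), "3")
  expect_identical(xml2::xml_attr(root, "version"), "1")
  expect_identical(xml2::xml_attr(root, "required"), "true")
  expect_true("http://www.sbml.org/sbml/level3/version1/spatial/version1" %in%
              unlist(xml2::xml_ns(doc)))
})

test_that("exported XML is well-formed for an independent parser", {
  m <- add_species(nested_model(c(16, 16, 16), radii = c(6, 3)), "A", "Cyt", 1)
  f <- withr::local_tempfile(fileext = ".xml")
  export_sbml(m, f)
  script <- sprintf(
    "from lxml import etree; d = etree.parse(%s); import sys; sys.exit(0 if d.getroot().tag.endswith('sbml') else 1)",
    shQuote(f))
  expect_identical(system2("python", c("-c", shQuote(script)),
                           stdout = FALSE, stderr = FALSE), 0L)
})

test_that("export/import round trip preserves geometry and model lists", {
  m <- nested_model(c(18, 18, 18), radii = c(6, 3))
  m <- add_species(m, "A_cyt", "Cyt", 1.0)
  m <- add_species(m, "A_ec", "EC", 0.0)
  m <- add_spatial_parameter(m, "k1", 0.5)
  m <- add_spatial_parameter(m, "D_A", 1e-12, role = "diffusion", species = "A_cyt")
  m <- add_spatial_parameter(m, "v_A", 2e-9, role = "advection",
                             species = "A_cyt", axis = "x")
  m <- add_spatial_parameter(m, "bc_A", 0, role = "boundary-condition",
                             species = "A_ec", axis = "Xmax")
  m <- add_reaction(m, "transport", "A_cyt", "A_ec", "k1*A_cyt",
                    membrane_local = TRUE, compartment = "PM")
  f <- withr::local_tempfile(fileext = ".xml")
  export_sbml(m, f)
  m2 <- import_sbml(f)
  expect_identical(m2$geometry$grid, m$geometry$grid)
  expect_identical(m2$geometry$value_map, m$geometry$value_map)
  expect_equal(m2$geometry$spacing, m$geometry$spacing)
  expect_equal(m2$domains[order(m2$domains$id), ],
               m$domains[order(m$domains$id), ], ignore_attr = TRUE)
  expect_equal(m2$species, m$species, ignore_attr = TRUE)
  expect_equal(m2$parameters, m$parameters, ignore_attr = TRUE)
  expect_identical(length(m2$reactions), length(m$reactions))
  expect_identical(m2$reactions[[1]]$rate, m$reactions[[1]]$rate)
  expect_identical(m2$reactions[[1]]$reactants, m$reactions[[1]]$reactants)
  expect_true(m2$reactions[[1]]$membrane_local)
  # adjacency edges agree as unordered pairs
  canon <- function(e) {
    a <- pmin(e$domain1, e$domain2); b <- pmax(e$domain1, e$domain2)
    sort(paste(a, b))
  }
  expect_identical(canon(m2$graph$edges), canon(m$graph$edges))
  # a second round trip is a fixed point
  f2 <- withr::local_tempfile(fileext = ".xml")
  export_sbml(m2, f2)
  m3 <- import_sbml(f2)
  expect_identical(m3$geometry$grid, m2$geometry$grid)
  expect_equal(m3$species, m2$species, ignore_attr = TRUE)
})

test_that("import rejects wrong level/version, missing spatial package, malformed XML", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level2/version4\" ",
                    "level=\"2\" version=\"4\"><model id=\"m\"/></sbml>"), f)
  err <- tryCatch(import_sbml(f), error = identity)
  expect_s3_class(err, "imgsbml_input_error")
  expect_match(conditionMessage(err), "Level")

  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
                    "level=\"3\" version=\"1\"><model id=\"m\"/></sbml>"), f2)
  err2 <- tryCatch(import_sbml(f2), error = identity)
  expect_s3_class(err2, "imgsbml_input_error")
  expect_match(conditionMessage(err2), "spatial")

  f3 <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml level=\"3\"", f3)
  expect_error(import_sbml(f3), class = "imgsbml_input_error")
})

test_that("export refuses an invalid model unless forced", {
  m <- nested_model(c(16, 16, 16), radii = c(6, 3))
  m$domains$x[m$domains$id == "Nuc0"] <- 0L   # interior point moved into EC
  m$domains$y[m$domains$id == "Nuc0"] <- 0L
  m$domains$z[m$domains$id == "Nuc0"] <- 0L
  f <- withr::local_tempfile(fileext = ".xml")
  expect_error(export_sbml(m, f), "validation", class = "imgsbml_input_error")
  expect_silent(export_sbml(m, f, force = TRUE))
  expect_true(file.exists(f))
})

test_that("kinetic-law MathML round-trips arithmetic, powers and functions", {
  for (expr in c("k1 * A", "a + b * c", "(a + b)/c", "a^2 - b", "-a + exp(b) * 2")) {
    norm <- imgsbml:::normalize_math(expr)
    node <- xml2::read_xml(imgsbml:::math_to_mathml(norm))
    expect_identical(imgsbml:::mathml_to_math(node), norm)
  }
})
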