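Package: imgsbml
Title: Spatial SBML Models from Segmented Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts segmented (binary) 2D and 3D microscopy masks into valid
    SBML Level 3 Version 1 documents carrying the Spatial Processes package.
    Provides mask preprocessing (hole filling, inter-region gap filling,
    nearest-neighbour z-interpolation of anisotropic stacks), merging of
    per-component masks into a single grayscale sampled-field geometry,
    3D connected-component domain labeling, automatic domain-adjacency
    resolution with zero-thickness membrane creation, model editing (species,
    spatial parameters, reactions), offline syntactic and spatial-semantic
    validation, and a command-line interface. Includes a deterministic
    synthetic-mask generator for testing without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tiff,
    xml2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
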