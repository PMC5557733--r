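Package: mandmap
Title: Surface-Based Micro-CT Morphometry of the Rodent Mandible
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Surface-based three-dimensional morphometry for detecting
    localized skeletal shape differences between two groups of specimens
    imaged by micro-computed tomography. Provides seeded GrowCut
    segmentation of bone from micro-CT volumes, isosurface extraction to
    triangulated meshes, landmark-based coordinate standardization
    (mental-foramen origin, occlusal-plane-parallel horizontal plane),
    thin-plate-spline guided fitting of a fixed-topology template mesh
    into homogeneous corresponding-point models, per-node group averages,
    per-axis displacement and significance-probability maps from
    two-sample t-tests, accentuated group averages, and per-region summary
    tables. A parametric hemimandible simulator with known displacement
    fields makes every pipeline stage testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils,
    tools,
    grDevices,
    ggplot2,
    RNifti,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
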