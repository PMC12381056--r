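Package: circletOD
Title: Optic Disc Localization and Segmentation in Fundus Images via the
    Fast Circlet Transform
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Unsupervised localization and segmentation of the optic disc in
    retinal fundus photographs. Combines patch-wise Fast Circlet Transform
    coefficients (frequency-domain detection of circular structures at optic-cup
    radii) with blood-vessel entropy features, fuses them through Minkowski
    weighted K-means feature weighting, and segments the disc boundary with a
    Chan-Vese level set after PDE-based vessel inpainting. Includes evaluation
    metrics (normalized center distance, Dice, Jaccard) and a seeded synthetic
    fundus-phantom generator with exact ground truth for download-free testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    cluster,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
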