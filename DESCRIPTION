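Package: rodseg
Title: Trainable Segmentation and Morphometrics of Enamel Rods in SEM Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A machine-vision pipeline for quantitative analysis of tooth
    enamel microstructure in scanning electron micrographs. Pixels are
    expanded into high-dimensional descriptors by the frozen convolutional
    layers of a VGG16-style network (pooling and activation layers omitted,
    so every layer stays at full image resolution) and classified into rod
    versus background by a random forest. Segmented masks are converted to
    per-rod morphometric tables (moment-fit ellipse axes, pitch, yaw,
    solidity), rods are classified into parazone and diazone bands, and
    cross-band pitch profiles are extracted. Validation tools register rod
    tables by centroid proximity and score paired pitch values against the
    identity line. A seeded synthetic enamel-image generator with
    pixel-exact ground truth makes the whole pipeline testable without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    tiff,
    png,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
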