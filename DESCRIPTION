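Package: paddygeom
Title: Geometric Identification of Paddy Seed Varieties from Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based identification of visually similar paddy (rice) seed
    varieties from single-seed colour images. Implements dual-band (red and
    hue) Otsu segmentation, Moore-neighbour contour tracing, key-point shape
    analysis of the seed outline (longest chord, perpendicular chords, convex
    hull and the two chaff-tip concavities), a seven-feature geometric
    descriptor, a one-hidden-layer backpropagation neural network classifier
    with a Gaussian Bayes comparator, confusion-matrix evaluation, and a
    synthetic silhouette generator with closed-form ground truth for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
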