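Package: plaquescope
Title: Quantification of Amyloid-Beta Pathology in Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable re-implementation of a convolutional
    neural network pipeline for quantifying amyloid-beta pathology (cored
    plaques, diffuse plaques, and cerebral amyloid angiopathy) in
    immunohistochemically stained whole-slide images. Provides Reinhard
    color normalization and lightness-chroma-hue tissue segmentation, a
    compact six-layer convolutional classifier with stride-16
    sliding-window confidence-heatmap inference, conversion of heatmaps
    into blob-density CNN scores (optionally restricted to a gray-matter
    mask), CERAD-style field-of-view scoring with top-n hotspot selection,
    and cohort-level statistical comparisons against ordinal pathology
    scores. A synthetic-slide generator with known ground truth makes every
    stage verifiable without institutional data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    mgcv,
    stats,
    grDevices,
    graphics,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
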