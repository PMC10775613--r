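Package: corneaseg
Title: Unsupervised Corneal Contour Extraction from Dynamic Deformation Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts corneal contours from air-puff corneal deformation videos
    (ultra-high-speed Scheimpflug recordings) without manual annotation. Each
    frame is pre-grouped into SLIC superpixels, segmented by a six-layer fully
    convolutional network trained unsupervised with a shape-factor-augmented
    cross-entropy loss, and the corneal region is selected by its shape factor
    before Moore-neighbour boundary tracing. Consecutive frames warm-start from
    the previous frame's network parameters (the shared model), which speeds up
    convergence and resists noise. Includes a synthetic corneal-video generator
    with per-frame ground truth, IoU/overlap-error evaluation, and classical
    thresholding/edge-detection baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
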