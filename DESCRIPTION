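Package: focalwave
Title: Multiscale Oriented Wavelet Analysis of Fluorescence Cell Image Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous wavelet analysis of fluorescence time-lapse microscopy
    across spatial scales, from the optical resolution limit to whole-cell
    morphology. Implements isotropic (Mexican hat) and anisotropic oriented
    (stretched) wavelet transforms with forward and inverse numerics on
    refined and coarsened meshes; detection of elongated focal adhesions as
    oriented-wavelet coefficient maxima with greedy non-overlapping ellipse
    placement; frame-to-frame adhesion linking; cell-boundary extraction from
    coarse-scale reconstructions with protrusion/retraction kinematics;
    constrained two-Gaussian mixture tracking of intra-adhesion
    sub-populations and their dynamic classification; a three-method
    consensus peak detector for two-channel actomyosin bundle pole
    velocimetry; and a ground-truthed synthetic movie generator for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
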