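Package: zfcardio
Title: Deep-Learning-Assisted Cardiac Function Analysis for Larval Zebrafish Heart Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cardiac function of larval zebrafish from fluorescence
    heart-beat videos. Provides a synthetic beating-heart simulator with exact
    ground truth, a ventricle segmentation network (recurrent residual
    convolutional units, two-level skip fusion, attention gates and atrous
    spatial pyramid pooling on a U-Net backbone) together with a classical
    threshold baseline, geometric extraction of end-diastolic/end-systolic
    areas and minimum-area-rectangle axes, fractional area change, fractional
    shortening, stroke volume and heart rate, a 1-D convolutional heart-rate
    estimator with an inception stage, and a phenotypic-screening layer that
    scores compounds by per-parameter rescue indices and an efficacy score
    with hit calling. Networks are trained with a compact reverse-mode
    automatic-differentiation engine included in the package.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
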