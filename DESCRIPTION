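Package: contourqa
Title: Uncertainty-Aware Quality Assurance for Organ Contours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Slice-level quality assurance for organ segmentation contours in
    radiotherapy workflows. A structure-conditioned residual convolutional
    network classifies paired image/binary-mask slices as acceptable or
    revision-required, Monte-Carlo dropout with normalized predictive entropy
    quantifies the confidence of each decision, and a recall-targeted
    calibration procedure derives per-structure uncertainty thresholds so that
    low-uncertainty predictions can be auto-accepted at a guaranteed
    sensitivity while uncertain contours are flagged for human review.
    Includes a synthetic phantom generator and the four mask perturbation
    families (dilation, erosion, translation, boundary noise) used to
    manufacture revision-required training examples, so the whole pipeline
    runs end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    mgcv,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
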