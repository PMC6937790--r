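Package: ctgcnn
Title: Computer-Aided Detection of Fetal Acidemia from Cardiotocographic
    Heart-Rate Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end pipeline for screening intrapartum fetal acidemia
    from 4 Hz fetal heart-rate (FHR) recordings labelled by umbilical-artery
    pH. Implements rule-based artifact removal (missing-signal gap
    interpolation, spike bridging to the next stable section, restoration of
    non-physiological values), continuous wavelet transform scalograms
    rendered as fixed-resolution RGB images, a small eight-layer
    convolutional neural network trained from scratch with stochastic
    gradient descent, stratified ten-fold cross-validation, and
    confusion-matrix metrics (accuracy, sensitivity, specificity,
    geometric-mean quality index, ROC AUC). A seeded synthetic
    cardiotocography simulator with ground-truth artifact masks allows the
    whole pipeline to be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    png,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
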