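Package: amwnet
Title: Adaptive Multi-Scale Attention Networks for Plant Leaf Disease Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and trains a convolutional classifier for leaf-disease
    images around three custom components: an adaptive residual pyramid
    convolution block with squeeze-and-excitation gating (ARPC), a triplet
    orientation attention module with a local-window branch for minute lesions
    (MTDFA), and a class-weighted focal loss with L2 regularisation (WfrLoss).
    Learning-rate search is performed by a tent-chaos initialised hybrid of the
    snow ablation optimizer and particle swarm optimization (TPSAO). Includes a
    seeded synthetic lesion-image generator, stratified splitting and
    augmentation, confusion-matrix metrics with a k-fold harness, and a small
    reverse-mode autodiff engine with C++ convolution kernels that powers the
    network blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    png,
    jsonlite,
    yaml,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    caret,
    optparse
Config/testthat/edition: 3
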