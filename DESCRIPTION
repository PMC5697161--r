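Package: csresnet
Title: Cost-Sensitive Residual Networks for Imbalanced Ocular Image Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for diagnosing posterior capsular
    opacification (PCO) severity from retro-illumination ocular images under
    heavy class imbalance. Provides circular lens localization by twice-applied
    Canny edge detection and Hough circle transformation, a cost-sensitive
    softmax cross-entropy loss with its analytic gradient and mini-batch
    gradient-descent trainer, batch-normalized bottleneck residual network
    building blocks, data-level rebalancing baselines (SMOTE,
    borderline-SMOTE, random under-sampling), conventional texture-feature
    baselines (local binary patterns, Haar wavelets, co-occurrence features),
    imbalance-aware evaluation metrics (sensitivity, specificity, F1, G-mean,
    ROC/PR/AUC), and the cost-factor grid-search protocol. A synthetic
    retro-illumination image generator with known lens geometry makes every
    component testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    randomForest,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
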