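Package: milgrade
Title: Attention-Based Multiple-Instance Learning for Ordinal Grading of
    Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Weakly supervised ordinal grading of H&E-stained gastric
    biopsy whole-slide images under the updated Sydney system. Provides
    tissue segmentation and non-overlapping 256x256 tiling of slide
    images, Macenko stain normalization, a pluggable patch-feature
    backbone contract, a gated attention-based multiple-instance network
    trained with an imbalance-aware (gradient-rebalanced) objective,
    stratified cross-validation and antrum-to-corpus fine-tuning,
    full-slide attention heatmaps, and the evaluation stack used for
    ordinal histological grading: macro one-vs-rest AUC, clinical utility
    index, quadratic weighted kappa, McNemar's, DeLong's and chi-squared
    tests. A synthetic graded-bag cohort generator with instance-level
    ground truth supports desk-scale experiments end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    pROC,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
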