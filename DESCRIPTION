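Package: mircervix
Title: Reciprocal-Pair miRNA Panel Scoring for Cervical Dysplasia
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for a six-miRNA RT-qPCR cervical dysplasia
    panel: control-reaction quality gating, reference-free reciprocal-pair
    delta-Ct predictors, a seeded bagged decision-tree ensemble with
    stratified k-fold out-of-fold scoring (the miR-CERVIX value in [0,1]),
    dual-threshold clinical interpretation, and diagnostic-performance
    evaluation (confusion metrics, ROC/AUC, Mann-Whitney and Kruskal-Wallis
    tests). Includes a synthetic Ct-level cohort generator so the whole
    pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
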