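Package: methylpls
Title: Sparse Partial Least Squares Discriminant Analysis for DNA
    Methylation Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds sparse partial least squares discriminant analysis
    (sPLS-DA) classifiers from Illumina methylation array beta-value
    matrices. Covers the full workflow: sample and probe quality control
    (inter-array correlation, sex concordance, SNP-probe contamination,
    detection p-value and bead-count filters, blocklists, non-variable
    probes), beta-mixture quantile (BMIQ) and between-sample quantile
    normalization, repeated stratified M-fold cross-validation with a
    keepX model-size sweep and feature-stability analysis, permutation
    controls, probability-calibrated prediction (softmax over prediction
    distances) with Youden's J threshold selection, and a seeded
    synthetic-cohort generator so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    limma,
    mixOmics,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
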