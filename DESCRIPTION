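Package: panelselect
Title: Blood Biomarker Panel Selection and Cross-Validated Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and honestly evaluating blood-based biomarker
    panels for case-control classification, with Alzheimer's disease serum and
    plasma panels as the motivating application. Provides a Gaussian-copula
    generator for dual-fraction cohorts with log-normal marker marginals and
    target cross-fraction Spearman correlations; support-vector-machine
    recursive feature elimination scored by leave-one-out cross-validation;
    a repeated stratified k-fold cross-validation engine with averaged and
    rounded confusion matrices, six performance metrics, and a mean-squared-
    error overfitting diagnostic; group-difference and rank-correlation
    summaries; and an experiment grid comparing single-fraction, combined,
    feature-eliminated and PCA-reduced configurations under shared folds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
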