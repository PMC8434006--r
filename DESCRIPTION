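Package: betapca
Title: Reliability-Based Component and Feature Selection for PCA-Family
    Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the number of principal components and the features
    assigned to them with a Cronbach-type reliability criterion (beta) that
    thresholds component loadings through the standard normal distribution
    function, with an optional kernel-SVM margin extension for nonlinearly
    separated feature spaces. Provides four extraction backends (exact PCA,
    centroid-class PCA, stochastic-gradient PCA, and kernel PCA with
    feature-score pseudo-loadings), the classical Kaiser and scree baselines
    and their fusion, a seeded synthetic generator emulating an imbalanced
    four-class chemical-hazard sensor dataset (toxic, physicochemical and
    network-security feature groups), an occupational mixture-exposure index
    with a configurable risk ladder, and a benchmark harness (stratified
    cross-validation, balanced accuracy, pairwise Wilcoxon signed-rank
    comparison tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
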