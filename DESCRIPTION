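Package: infolasso
Title: Integrated Mutual-Information Ranking and Penalty-Free Lasso
    Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sparse classification for small-sample, high-dimensional
    biomedical feature tables (for example cortical-thickness measures over
    atlas regions of interest). Features are first ranked by their mutual
    information with a binary class label and pruned for pairwise
    correlation; the top-ranked candidates are then placed penalty-free in a
    generalized (per-coefficient weighted) lasso, solved by a projection
    reduction to a standard lasso, and penalty-free subsets are searched by
    leave-one-out cross-validation. Includes mutual-information baseline
    selectors (MIM, MIFS, MRMR, JMI, CMIM), Pudil's floating search, a
    PCA-based reduction, L1-penalized logistic regression, and a seeded
    synthetic-data generator with a benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
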