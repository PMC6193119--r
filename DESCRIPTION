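Package: connstates
Title: Static, Dynamic and Structural Brain Connectivity with Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted brain-connectivity graphs from node time series and
    fiber-probability matrices and compares them between groups. Implements static
    functional connectivity (Pearson correlation, unsigned soft thresholding,
    Fisher r-to-z, degree centrality), sliding-window dynamic connectivity with an
    L1-penalised Gaussian precision estimator (graphical lasso) and K-means
    brain-state discovery, directed structural degree centrality, betweenness-based
    hub identification, permutation group tests with Benjamini-Hochberg false
    discovery rate control, and regressions of centrality against eating-disorder
    questionnaire scores with an age covariate. A synthetic-cohort generator with
    planted states, group effects and behaviour scores provides ground truth for
    end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
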