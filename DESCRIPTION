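Package: netstab
Title: Accuracy and Stability of Regularized Partial Correlation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates Gaussian graphical models (regularized
    partial-correlation networks) from ordinal or continuous data using
    polychoric correlations and the graphical lasso with extended BIC
    model selection, computes weighted-network centrality indices
    (strength, closeness, betweenness), and quantifies how accurately
    a network is estimated: nonparametric and parametric bootstrapped
    confidence intervals for edge weights, the case-dropping subset
    bootstrap with the correlation-stability (CS) coefficient, and
    bootstrapped difference tests for edge weights and centralities.
    Includes a simulator for chain (ring) networks with Watts-Strogatz
    rewiring and ordinalization, used to study the calibration of the
    difference tests and the behaviour of the CS coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mvtnorm
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
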