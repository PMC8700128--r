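Package: connbench
Title: Benchmarking Correlation and Causality Measures for Multivariate Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates five-variate nonlinear stochastic systems with known
    contemporaneous and lagged (causal) dependency structure and benchmarks ten
    connectivity estimators against them: partial Pearson and Spearman
    correlation, (partial) distance correlation, k-nearest-neighbour mutual
    information, conditional Granger causality (full and restricted VAR),
    partial directed coherence, transfer-entropy style measures on non-uniform
    mixed embeddings, and constraint-based lagged plus contemporaneous causal
    discovery. Includes the matching significance machinery (parametric t and F
    tests, permutation and time-shift surrogate tests) and a harness that
    aggregates detection percentages over realizations into publication-style
    tables and scores them against the known truth networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
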