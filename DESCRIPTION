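Package: lumenet
Title: Multi-View Sparse Canonical Correlation and Exposure-Stratified
    Network Analysis for Environmental Epidemiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-step inference pipeline linking a scalar environmental
    exposure (nighttime light emission on the DMSP/OLS digital-number
    scale) to grouped urban-feature measures and individual wellbeing
    factors. Step one is multi-view sparse canonical correlation analysis
    with stability selection under random sparsity, an unpenalized refit
    on the stable variables, hold-out validation and permutation testing.
    Step two estimates exposure-stratified Gaussian graphical models via
    a graphical-lasso path with extended-BIC model selection and greedy
    stepwise refinement, computes 1-step bridge expected influence,
    assesses stability by case-dropping bootstrap, and compares strata
    with a permutation network comparison test. A synthetic multi-view
    data generator with planted latent structure provides ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
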