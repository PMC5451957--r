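Package: pestmix
Title: Bayesian Profile Regression and Mixture Analysis of Residential
    Agricultural Pesticide Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for joint-exposure ("multipollutant") analysis of
    residential proximity to agricultural pesticide applications.  Builds
    per-subject pregnancy-average use estimates from use-report records via
    1-km buffer area weighting, discretizes them into quartile profiles,
    clusters the profiles with an outcome-supervised Dirichlet-process
    mixture model (Bayesian profile regression) fit by a blocked Gibbs
    sampler, characterizes clusters against a low-exposure reference,
    ranks pesticide classes with a Gaussian kernel machine model under
    hierarchical variable selection, and tests spatial autocorrelation of
    use and outcome with global and local Moran's I.  Includes a synthetic
    use-report scenario generator with planted cluster structure so the
    whole pipeline is testable without confidential cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    MASS,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ape,
    withr
Config/testthat/edition: 3
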