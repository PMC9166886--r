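Package: rsdfm
Title: Regime-Switching Dynamic Factor Models for Intensive Longitudinal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a two-level nonlinear dynamic factor model for intensive
    longitudinal data in which latent AR(1) within-person states drive a
    hidden two-state Markov switching process with covariate-dependent
    transition probabilities. Provides a native Gibbs sampler for the full
    posterior (factor scores, random effects, partly observed discrete state
    paths, and all measurement, structural and switching parameters), a
    forward-filtering forecaster over the four regime-transition strata of
    the corresponding mixture of dynamic linear models (with H-steps-ahead
    forecast distributions for both continuous latent factors and discrete
    latent states), a synthetic-data generator that emulates the generative
    model, and a simulation-study harness reporting state-extraction
    sensitivity/specificity, forecast-interval coverage and width, and a
    quadratic forecast score.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    coda,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
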