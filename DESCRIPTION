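Package: pwabc
Title: Piecewise Approximate Bayesian Computation for Discretely Observed
    Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood-free Bayesian inference for Markov models observed at
    discrete time points. The posterior is factorised over consecutive
    observation pairs; each factor is targeted by rejection ABC with the
    identity summary statistic and a small (or zero) tolerance, and the
    factors are recombined either through a closed-form product of Gaussian
    approximations or through kernel density estimates evaluated on a lattice
    in log space. Includes marginal-likelihood estimation, exact-posterior
    oracles for tractable models (binomial, Cox-Ingersoll-Ross, INAR(1)),
    a Gillespie simulator for a stochastic Lotka-Volterra system, and
    tidy/broom-style accessors with ggplot2 visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
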