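Package: pigdice
Title: Simulation and Cognitive Modelling of Sequential Risk Taking in the
    'Pig' Dice Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how switch value and choice conflict shape
    sequential decisions under risk, using the 'pig' dice game as the model
    paradigm. Provides a generative task simulator with expected-utility
    softmax agents and analytic indifference points, hierarchical Bayesian
    logistic and response-time regressions (via JAGS) with indifference-point
    and choice-conflict estimation, a family of diffusion decision models with
    trial-wise drift, threshold, and starting-point modulation fitted by
    adaptive MCMC on an exact Wiener first-passage likelihood, WAIC model
    comparison, posterior predictive checks, and a reproducible pipeline with
    data quality gates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    rjags,
    coda,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
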