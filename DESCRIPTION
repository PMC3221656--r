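Package: countpref
Title: Hierarchical Bayesian Analysis of Choice Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian modelling of replicated choice count data
    (for example oviposition preference experiments), in which each
    replicate's counts are multinomial with its own preference vector and
    those vectors are drawn from a population-level Dirichlet distribution
    whose mean and concentration are estimated separately.  Provides a
    Metropolis-within-Gibbs MCMC sampler, posterior summaries with pairwise
    exceedance probabilities, deviance information criterion (DIC) model
    comparison for constrained-preference and population-grouping models,
    the classical Friedman, Quade and arcsine-square-root ANOVA comparators,
    and a null-simulation calibration study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
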