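Package: mtmeval
Title: Multi-Trait Multi-Environment Genetic Evaluation of Progeny Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genetic evaluation of segregating progeny tested in multi-environment
    trials, with single-trait and multi-trait mixed models fitted both by
    restricted maximum likelihood (EM-REML with Henderson mixed-model equations,
    BLUP, prediction error variance, AIC and likelihood-ratio tests) and by
    Bayesian Gibbs sampling with inverse-Wishart/inverse-gamma priors (chain
    diagnostics, highest posterior density intervals, DIC). Includes derived
    genetic parameters (plot-basis broad-sense heritability, coefficients of
    variation, selection accuracy, genetic correlations including the
    sum-of-traits covariance trick), progeny ranking and selection statistics
    (predicted gain, Spearman agreement with bootstrap intervals, coincidence
    index, additive genetic index), and a balanced randomized-complete-block
    trial simulator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    coda,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
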