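Package: glmmscore
Title: Bayesian Predictive Model Evaluation for Longitudinal Count GLMMs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for choosing among rival Bayesian generalized linear mixed
    models for longitudinal count endpoints, as used when shaping the
    sensitivity analyses of a clinical trial. Fits Poisson, negative binomial,
    zero-inflated (ZIP/ZINB) and arcsinh-transformed normal mixed models by
    adaptive MCMC, and evaluates them with leave-one-out predictive criteria:
    the conditional predictive ordinate (CPO) via full-data ghost sampling or
    exact single-case refits, the logarithmic score, non-randomized probability
    integral transforms (PIT) for count outcomes, and DIC. Includes paired
    Monte Carlo permutation tests for mean-score differences, AUC summaries of
    score separation across simulation replicates, a negative binomial
    longitudinal data generator, and an end-to-end simulation study of the
    discriminatory power of DIC and the mean logarithmic score.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
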