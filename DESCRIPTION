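Package: recruitflow
Title: Interim Recruitment Monitoring and Forecasting for Multi-Center
    Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for monitoring, modeling, and predicting patient
    recruitment in multi-center clinical trials. Provides one-sided tests
    for decay in recruitment rates (a Poisson likelihood-ratio test and a
    non-parametric within-center bootstrap test) with a Monte-Carlo power
    study harness; a family of inhomogeneous Poisson-gamma recruitment
    models with normalized, monotonically decaying intensity curve-shapes
    indexed by a tail parameter kappa; Bayesian inference via importance
    sampling with a multivariate-t proposal, marginal likelihoods, and
    Bayesian model averaging over the curve-shape family; exact conjugate
    posterior-predictive simulation of future accrual paths and
    time-to-target distributions; QQ model diagnostics; and a trial
    simulator for power studies and method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
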