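Package: visitjm
Title: Joint Models for Longitudinal Markers with Informative Visit Times
    and Competing Risks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Shared-parameter joint models for a Gaussian longitudinal
    marker observed at irregular, possibly informative visit times, with
    terminal events in the form of competing risks. The visiting process
    may be specified on the gap-time or calendar-time scale, with cubic
    B-spline log-baseline hazards, history-dependent covariates,
    association with the latent baseline marker value and slope, and an
    optional gamma frailty. Estimation is by marginal maximum likelihood
    with pseudo-adaptive Gauss-Hermite or Monte Carlo integration over
    the random effects, an analytic score, BFGS optimization, and
    inverse-Hessian standard errors. Includes a scenario simulator for
    informative-visiting mechanisms and a simulation-study harness
    reporting bias, MSE, average model-based standard errors, Monte
    Carlo standard deviations, and coverage.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    splines,
    lme4,
    lhs,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
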