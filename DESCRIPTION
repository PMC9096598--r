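Package: adaptsim
Title: Bayesian Goldilocks and Group-Sequential Adaptive Trial Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Specification, virtual execution and Monte-Carlo evaluation of
    two adaptive designs for two-arm randomized trials with a binary 90-day
    primary outcome and an earlier 6-week assessment: a Bayesian
    "Goldilocks" sample-size-selection design using predictive
    probabilities of trial success with a longitudinal early-endpoint
    imputation model and binding futility, and a frequentist
    group-sequential design with Gamma-family (Hwang-Shih-DeCani)
    error-spending efficacy and futility boundaries.  Includes a seeded
    patient-level trial simulator with staggered accrual and
    snapshot-censored outcomes, operating-characteristic estimation
    (type I error, power, expected sample size, stop probabilities),
    posterior-superiority computation by deterministic quadrature, and
    journal-style unadjusted risk-difference reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
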