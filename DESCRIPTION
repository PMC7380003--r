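Package: persched
Title: Personalized Biopsy Schedules for Active Surveillance via Joint Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scheduling surveillance biopsies for low-risk prostate
    cancer patients under active surveillance. A joint model links a
    mixed-effects trajectory for log-scale PSA to a relative-risk model for the
    interval-censored time of Gleason reclassification, with the PSA level and
    velocity entering the log hazard. From a patient's accumulated PSA
    measurements and negative biopsies the package computes the posterior
    predictive distribution of the reclassification time and derives
    personalized biopsy times from decision-theoretic loss functions (expected
    time, median time, dynamic-risk threshold, and a hybrid rule), alongside
    fixed annual and PRIAS comparators. Includes a cohort simulator with
    subgroup-specific Weibull baseline hazards, an F1-score based selection of
    the dynamic-risk threshold, an interval-censored MCMC fitter, and a
    simulation framework that scores schedules by biopsy burden and detection
    delay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    splines,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
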