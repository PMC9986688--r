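Package: prscalib
Title: Calibrating Polygenic Risk Scores to an Age-Dependent Polygenic
    Hazard Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for incorporating an arbitrary breast-cancer polygenic
    risk score (PRS) into a polygenic hazard model in which the total
    polygenic variance of the log-hazard declines linearly with age.  The
    key calibration parameter is alpha, the square root of the proportion
    of the age-dependent polygenic variance explained by the PRS.  The
    package provides three estimators of alpha: a transformed-covariate
    logistic regression, a retrospective likelihood that integrates over
    the unmeasured residual polygenic component, and a proportionality
    calibration against a reference PRS.  It also provides PRS weight-file
    parsing and genotype scoring, incidence-constrained baseline-hazard
    computation, and a model-faithful case-control cohort simulator for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
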