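Package: mchtrends
Title: Two-Stage Small-Area Estimation of Maternal and Child Health Trends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates subnational (state-level) annual trends in maternal and
    child health intervention coverage and under-5 mortality from sparse,
    irregular household-survey data. Survey microdata are tabulated into
    design-weighted state-year estimates, harmonized (card-versus-recall
    immunization crosswalks, birth-year attribution, pre-policy imputation),
    and synthesized with a two-stage model: a mixed-effects regression on the
    logit scale with spline time trends and state/zone random effects selected
    by hold-out cross-validation, followed by Gaussian process regression with
    a Matern covariance that produces posterior draws of each state's trend.
    Includes draw-level population-weighted national aggregation, an
    equally-weighted composite coverage index, a complete-birth-history
    under-5 mortality stage, and a synthetic-data generator with known truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lme4,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
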