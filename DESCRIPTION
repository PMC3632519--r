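Package: cohortsynergy
Title: Additive Interaction Analysis of Diabetes Risk in Cross-Sectional Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether two risk factors act synergistically on
    the prevalence odds of disease in a cross-sectional cohort. Provides typed
    participant-level cohort input/output with an explicit codebook, deterministic
    classification of diabetes, impaired fasting glucose (prediabetes) and derived
    binary exposures (parental history of diabetes, smoking, physical inactivity,
    adiposity cut-offs including sex-specific 90th percentiles), prevalence odds
    ratios from logistic regression with Wald confidence intervals, and additive
    interaction measures: Rothman's synergy index S, the relative excess risk due
    to interaction (RERI) and the attributable proportion (AP), each with
    delta-method confidence intervals and an optional bootstrap. A seeded
    synthetic-cohort generator with a configurable joint-exposure odds structure
    supports calibration, coverage and parameter-recovery studies, and a pipeline
    layer produces descriptive, odds-ratio and interaction report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    readr,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
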