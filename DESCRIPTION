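Package: hipecpk
Title: Noncompartmental Pharmacokinetics and Hematological Toxicity of
    Carboplatin HIPEC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intraperitoneal chemotherapy exposure from
    dual-matrix (perfusate and plasma) concentration-time data collected
    during hyperthermic intraperitoneal chemotherapy (HIPEC) with
    carboplatin. Implements noncompartmental analysis (Cmax, lambda-z
    terminal-slope estimation with adjusted-R-squared window selection,
    windowed trapezoidal AUCs, and the intraperitoneal-to-plasma AUC
    ratio), geometric-mean cohort summaries with t-based confidence
    intervals, a log-scale two-sample comparison of exposure ratios between
    peritonectomy-extent groups, and CTCAE v4.0 grading of hematological
    toxicity from serial complete blood counts. A two-compartment
    perfusate-to-plasma kinetic simulator with lognormal interindividual
    variability, proportional assay error, and lower-limit-of-quantification
    censoring generates realistic synthetic cohorts so the whole pipeline
    can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
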