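Package: parrisk
Title: External Validation Toolkit for Points-Based Readmission Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to externally validate points-based clinical risk scores
    for potentially avoidable hospital readmission (PAR) on electronic health
    record style data. Extracts the twelve PAR-Risk Score predictors from
    admission, diagnosis (ICD-10), drug dispensing (ATC), laboratory and
    prior-admission tables; computes raw scores and risk groups under original
    and tertile-adapted thresholds; evaluates discrimination (C statistic with
    DeLong confidence interval), accuracy (Brier score), global goodness of
    fit (le Cessie-van Houwelingen-Copas-Hosmer unweighted sum-of-squares
    test) and calibration; derives contingency-table odds ratios and
    classification metrics per risk group; and ships a reproducible synthetic
    EHR cohort generator so every pipeline stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
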