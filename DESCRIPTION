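Package: pedtriage
Title: External Validation and Updating of a Pediatric Triage Risk Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring children with a nine-predictor logistic triage
    model, externally validating it (discrimination, calibration, overall
    accuracy), updating it by a three-step recalibration and revision cascade,
    selecting risk thresholds, and stratifying patients into three triage
    categories. Includes a synthetic-cohort generator that emulates the
    structure of multi-site pediatric outpatient data (age-group mixture,
    site-level baseline-risk shifts, low-rate missingness), sample-size
    calculators for planning validation cohorts, and report and table
    renderers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
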