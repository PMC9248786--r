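Package: pahlot
Title: Treatment Lines, Utilization, and Costs from Administrative Claims in
    Pulmonary Arterial Hypertension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacoepidemiologic treatment-pattern
    analysis of pulmonary arterial hypertension (PAH) in longitudinal
    administrative claims: cohort selection by sequential attrition with an
    index date at the first PAH medication claim, line-of-therapy segmentation
    from days'-supply coverage intervals with interruption / modification /
    censoring semantics, mutually exclusive regimen classification across six
    medication classes, and all-cause and PAH-related healthcare resource
    utilization and per-patient-per-month cost summaries in inflation-adjusted
    dollars. Ships a seeded trajectory-first synthetic claims generator with a
    planted answer key so every stage can be validated end to end without
    access to proprietary claims data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
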