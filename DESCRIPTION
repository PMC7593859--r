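Package: ceapipe
Title: Incremental Cost-Effectiveness Analysis for Community Health Programs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the economic evaluation of community
    health-worker programs evaluated in two-arm cluster trials with birth
    and infant-mortality surveillance. Provides incremental program costing
    with discounted annuity-based capital annualization, intention-to-treat
    and per-protocol cohort construction from birth-level surveillance
    records, the full incremental cost-effectiveness panel (cost per 1000
    live births, per infant death averted, per life-year saved) with
    GDP-per-capita threshold classification and an equivalent two-arm
    decision tree, deterministic scenario sensitivity analysis, and a
    synthetic-data generator that emulates the surveillance and accounting
    structure of such trials for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
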