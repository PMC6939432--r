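Package: baricea
Title: Cost-Effectiveness Modelling of Bariatric Surgery for Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort cost-effectiveness pipeline comparing bariatric
    surgery with conventional medication therapy for obese patients with
    type 2 diabetes, from a health-insurance payer perspective. Provides
    synthetic patient-cohort generation with confounded treatment
    assignment, propensity-score matching with calliper-restricted 1:1
    nearest-neighbour pairing and covariate balance diagnostics, a
    three-state (remission / diabetes / death) annual-cycle Markov engine,
    discounted cost and QALY accumulation with incremental
    cost-effectiveness and dominance verdicts, diabetic versus non-diabetic
    mortality decomposition from whole-population statistics, and one-way
    (tornado) plus probabilistic sensitivity analyses with
    cost-effectiveness acceptability curves.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
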