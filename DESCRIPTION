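Package: phewasmr
Title: Phenome-Wide Survival Scans and Genotype-Area Instruments for
    Alcohol and Disease Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for cohort studies of alcohol
    consumption and hospitalized disease outcomes. Derives drinker status,
    weekly grams of ethanol and drinking-pattern flags from questionnaire
    fields; curates ICD-10 disease endpoints with a minimum-case rule and
    chapter-wise less-common pooling; fits age-at-risk- and area-stratified
    Cox proportional-hazards models with floating absolute risks and
    regression-dilution-corrected dose-response estimates; runs phenome-wide
    scans with Benjamini-Hochberg false-discovery control within ICD-10
    chapters; builds a two-variant genotype-by-area instrument for Mendelian
    randomization with area-stratified inverse-variance-weighted slope
    meta-analysis, sex-heterogeneity pleiotropy tests and a two-stage
    least-squares sensitivity analysis; and estimates cumulative
    hospitalization burden via the mean cumulative count under competing
    mortality. Includes a seeded synthetic-cohort generator that emulates the
    statistical structure such analyses assume, so the whole pipeline is
    testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    survival,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
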