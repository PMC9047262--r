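Package: swineamu
Title: Farm-Level Antimicrobial Use Quantification for Swine Herds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies antimicrobial use (AMU) on swine farms from
    questionnaire-style records of feed rations, water medications,
    injections and herd demographics. Estimates feed and water intake per
    pig, computes antimicrobial mass consumed per cohort, route and active
    ingredient, and converts exposure into frequency, weight-based (mg/kg
    biomass) and dose-based (defined daily doses per pig and per 1000
    pig-days) surveillance metrics by production stage. Includes
    descriptive health and biosecurity tables with exact binomial
    confidence intervals, and a seeded synthetic questionnaire generator
    with closed-form expected metrics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    readr,
    tibble,
    rlang,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
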