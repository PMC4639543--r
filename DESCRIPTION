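Package: headburden
Title: Headache Burden Estimation from Community Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing community-based headache surveys of the
    HARDSHIP family: a hierarchical ICHD-II rule-based diagnostic algorithm
    over questionnaire responses (migraine, tension-type headache, probable
    medication-overuse headache and other headache on >=15 days/month),
    symptom-burden and lost-productive-time summaries (HALT-style),
    ictal-state disability estimation with GBD disability weights,
    consultation/expenditure/willingness-to-pay summaries, and a seeded
    synthetic cohort generator calibrated to published marginal
    distributions so every pipeline stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
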