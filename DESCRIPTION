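Package: rorscreen
Title: Disproportionality Screening of Spontaneous Adverse Drug Reaction Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance analysis of Individual Case Safety
    Report (ICSR) line-lists: MedDRA preferred-term query sets for drug
    resistance and drug ineffectiveness, stratified descriptive tables,
    reporting odds ratio (ROR) disproportionality with Wald confidence
    intervals and a signal-of-disproportionate-reporting rule, and a seeded
    synthetic ICSR generator so every pipeline stage can be validated against
    known ground truth without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
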