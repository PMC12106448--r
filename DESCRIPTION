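Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance toolkit for mining spontaneous adverse event
    report databases in the FAERS quarterly ASCII dialect. Reads and assembles
    multi-table quarterly extracts, collapses multi-version cases to one record
    per case, partitions reports by a target-drug lexicon, maps preferred terms
    to system organ classes through a user-supplied term dictionary, and scans
    for disproportionate reporting with three algorithms (reporting odds ratio,
    proportional reporting ratio with chi-squared, and the relative reporting
    ratio with its lognormal lower bound) under joint signal criteria.
    Includes descriptive cohort tables, annual trend and gastrointestinal
    split summaries, sex and age subgroup scans with stratum-matched
    comparators, and a synthetic spontaneous-report generator with planted
    drug-event associations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
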