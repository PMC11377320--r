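Package: faersdpa
Title: Disproportionality Analysis of Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for pharmacovigilance signal detection on
    FAERS-style spontaneous adverse-event report data: quarterly ASCII
    table ingestion, report deduplication, primary-suspect drug cohorting,
    MedDRA PT/SOC aggregation, four disproportionality statistics
    (reporting odds ratio, proportional reporting ratio with chi-square,
    BCPNN information component, and the DuMouchel gamma-Poisson shrinker
    EBGM), configurable signal classification, and descriptive summaries
    (demographics, outcomes, annual counts, time to onset, indications).
    Includes a synthetic spontaneous-report generator with planted
    drug-event associations so every stage is testable without a database
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
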