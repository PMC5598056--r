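Package: detl
Title: Declarative Rule-Based ETL for Clinical Common Data Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A dynamic extract-transform-load (ETL) toolkit for harmonizing
    heterogeneous health data (electronic health record and claims extracts)
    into a common data model. Transformation logic is expressed as
    human-readable, 12-attribute mapping rules stored in CSV files; a rule
    engine compiles each rule into one executable INSERT...SELECT statement
    with automatic record de-duplication, conflict resolution by load
    timestamp, join and filter assembly, and per-rule provenance for
    debugging. Includes pre-load validation of extracted CSV data (type,
    required-field, length, and orphan foreign-key checks with error and
    warning severities), a staging loader with resumable batch execution on
    an embedded SQLite database, a reproducible synthetic claims and clinical
    data generator with a ground-truth anomaly ledger, and a command-line
    interface covering the validate, compile, and run workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    readr,
    tibble,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
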