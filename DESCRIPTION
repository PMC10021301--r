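Package: ctriaudit
Title: Audit of Ethics-Committee Data Quality in CTRI-Style Trial Registry Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the ethics-committee (EC) and trial-site data of
    records shaped like those of the Clinical Trials Registry-India (CTRI).
    Provides a record data model with an HTML parser and a plain-text relational
    snapshot format, a parameterised cohort-selection cascade, a site/EC count
    classifier, a scored site-EC matcher with elimination and ambiguity grading,
    a rule-based deficiency linter covering blank-EC, count-mismatch, repeated
    rows, generic or uninformative committee names, acronym collisions, and
    registration-time validation rules, and a synthetic record generator with
    controllable deficiency injection and ground truth for benchmarking every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    readr,
    tibble,
    xml2,
    stats,
    utils
Suggests:
    dplyr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
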