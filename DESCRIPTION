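Package: textpheno
Title: Depression Phenotyping from Electronic Health Records Combining
    Coded Diagnoses and Clinical-Note Text Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects evidence of depressive disorders in cancer-patient
    electronic health records by combining ICD-9-CM diagnosis codes with
    misspelling-tolerant dictionary mining of bilingual (Spanish/Catalan)
    free-text clinical notes, excluding negated mentions via a Conditional
    Random Field negation-scope tagger or a NegEx-style rule baseline.
    Classifies each patient's evidence per channel (codes, antidepressant
    mentions, disorder-term mentions) relative to the cancer-diagnosis
    index date, builds the paired before/after tables, and computes
    continuity-corrected McNemar and chi-square statistics. Includes a
    fully ground-truthed synthetic cohort generator (patients, visits,
    bilingual notes, annotated negation corpus) so the whole pipeline is
    testable without access to protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    stringi,
    tibble,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
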