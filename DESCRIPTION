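Package: hlhphenotype
Title: Computable Phenotypes and Treatment Outcomes for Hemophagocytic
    Lymphohistiocytosis from EHR Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares three rule-based computable phenotypes for
    hemophagocytic lymphohistiocytosis (HLH) over delimited-text electronic
    health record extracts: ICD-10 coding (D76.1/D76.2), HLH-named treatment
    plans, and an operationalized evaluation of the eight HLH-2004 clinical
    criteria per hospital episode (laboratory thresholds, a two-clause oral
    fever rule, and clinical-text term matching with a fixed-window negation
    rule). Downstream tooling classifies HLH-directed therapy exposure,
    derives clinical outcomes, runs the treated-versus-untreated comparison
    (Wilcoxon rank-sum, chi-square/Fisher, risk differences with Wald
    intervals, bootstrap median differences), and summarises a
    ferritin-plus-fever screening cohort. A seeded synthetic-EHR generator
    and deterministic count-placed fixtures make every stage testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
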