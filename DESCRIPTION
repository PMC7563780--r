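Package: melcohort
Title: Melanoma Cohort Genomics: Panel TMB, Genomic Subtypes and ICI
    Resistance Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing targeted-panel somatic variant cohorts of
    advanced melanoma. Implements an adjusted per-sample tumor mutational
    burden that avoids over-extrapolating variants in known tumor genes,
    genomic subtype classification into BRAF-, RAS-, NF1-mutated and triple
    wild-type, exact-test enrichment of gene alterations by histopathological
    subtype, Mann-Whitney burden comparisons, and a rule-based predictor of
    resistance to immune checkpoint inhibitors evaluated by 2x2 performance
    metrics and relative risk. Ships a deterministic reference cohort fixture
    and a stochastic cohort simulator so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
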