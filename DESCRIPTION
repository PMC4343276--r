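Package: methylALL
Title: DNA Methylation Subtype Classification and Copy-Number Calling for
    Pediatric Acute Lymphoblastic Leukemia
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains and applies nearest shrunken centroid (NSC) one-vs-rest
    classifiers on 450k-style DNA methylation beta values to call the
    recurrent cytogenetic subtypes of pediatric acute lymphoblastic
    leukemia, with consensus CpG selection by repeated stratified
    cross-validation, probability-threshold decision logic, nested external
    cross-validation for performance estimation, a copy-number-alteration
    caller from methylation array intensities (quantile normalization and
    log2 ratios against a non-leukemic reference panel, with IGV track
    export), and a synthetic cohort generator so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
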