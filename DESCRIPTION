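Package: conscreen
Title: Consensus Evidence Frameworks for miRNA Target Prediction and
    Ensemble Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating consensus-evidence pipelines
    in target discovery. Implements confusion-matrix validation metrics
    (accuracy, positive predictive value, false-positive rate), rank-based
    ROC/AUC for actives-versus-decoys benchmarks, multi-program
    miRNA-target consensus prediction with per-program threshold criteria,
    two-phase rank/re-rank conformer-ensemble virtual screening with
    valid-conformer selection and k-of-N consensus hit calling, a SAM-style
    two-class permutation FDR differential-expression filter, hypergeometric
    fold-enrichment annotation filtering, multi-source interaction-list
    integration, and seeded synthetic-data generators that reproduce the
    statistical structure each stage assumes so the whole pipeline can be
    exercised without external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
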