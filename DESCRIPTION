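Package: mabclar
Title: Dual-Scheme Subtyping and a Four-Gene AR-Target Signature for
    ER-Negative Breast Tumors
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the molecular convergence of the luminal
    androgen receptor (LAR) and molecular apocrine (MABC) subtypes of
    estrogen-receptor-negative breast cancer.  Provides generic
    correlation-to-centroid subtype classification (CIT-style six-class and
    TNBCtype-style schemes, including TNBCtype-6 to TNBCtype-4 conversion and
    second-best-centroid analysis), overlap and concordance statistics with
    confusion-matrix diagnostics, PI3K/AKT/mTOR pathway-activation flagging
    from genomic alteration tables (ERBB2 amplification kept distinct from
    gain), marker-mean microenvironment scoring, and a four-gene (AR, FOXA1,
    SPDEF, TFF3) signature in two platform-specific forms: a random-forest
    classifier on TBP-normalised RNA-seq features and an RT-qPCR 2^-dCT
    cut-off vote classifier with ROC-based (Youden J) cut-off selection.  A
    seeded synthetic ER-negative cohort generator with purity-weighted
    immune/fibroblast admixture, planted alterations and simulated qPCR CT
    values supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
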