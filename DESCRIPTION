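Package: PSMAhet
Title: Quantifying PSMA Expression Heterogeneity in Multi-Site Metastatic
    Prostate Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify inter- and intratumoral heterogeneity of
    immunohistochemistry marker expression (PSMA and related markers) in
    multi-site metastatic prostate cancer cohorts. Implements 3-level
    H-score computation and classification, the hypergeometric
    pair-difference heterogeneity probability with cluster-bootstrap BCa
    confidence intervals, multi-cohort differential-expression consensus
    with druggable-genome and surfaceome target refinement, COMPARE-MS
    qPCR methylation indices and region-level bisulfite methylation
    summaries, and a synthetic-cohort generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    matrixStats,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    boot
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
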