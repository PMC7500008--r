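Package: lymphomiR
Title: miRNA-Seq Signature Analysis of Lymphatic Dissemination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for miRNA-Seq count data that identifies
    expression signatures associated with lymph-node status in tumor
    cohorts. Provides between-sample normalization (TMM, RLE, upper
    quartile, total count) with concordance diagnostics, dual-test
    consensus differential expression combining a negative-binomial
    quasi-likelihood F-test with the Mann-Whitney test under
    Benjamini-Hochberg FDR control, high/low relative-expression
    frequency comparisons, per-sample composite signature scoring with
    G0/G1 dichotomization and Fisher-exact cohort enrichment, Spearman
    correlation-structure analysis of signature modules, and a seeded
    negative-binomial count simulator with ground truth for recovery
    benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
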