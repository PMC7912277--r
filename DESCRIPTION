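Package: scregulon
Title: Single-Cell Regulon Activity and Transcriptional Signature Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying transcription-factor regulon activity and
    pathway enrichment in single-cell RNA-seq data from cultured cell lines.
    Implements TPM and log normalization with gene filtering, per-gene
    mean-variance statistics with loess de-trending, Wilcoxon rank-sum
    differential expression with Benjamini-Hochberg correction, weighted
    Kolmogorov-Smirnov gene set enrichment and likelihood-weighted regulon
    enrichment with permutation-based normalized enrichment scores (NES),
    master regulator analysis, per-cell pathway and regulon activity
    scoring, cell-cycle phase assignment by expression-matched module
    scores, and pseudobulk-to-bulk matching by Spearman correlation.
    Includes a seeded negative-binomial count simulator with known ground
    truth (regulon-driven population differences, cell-cycle programs,
    planted high-variance genes, matched bulk profiles) for validating the
    full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
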