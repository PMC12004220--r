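Package: coexmod
Title: Co-Expression Gene Module Detection for Single-Cell and Spatial
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects modules of co-expressed genes in single-cell RNA-seq and
    spatial transcriptomics count matrices. Genes are scored by the distance to
    their Kth nearest neighbor (DKNN) in expression space, compared to a
    resampling null to derive an FDR-controlled selection threshold, organised
    into a nearest-neighborhood or reciprocal-neighborhood graph, and
    partitioned into modules with a Markov Cluster (MCL) implementation.
    Includes module filters (size, supporting cells, standard deviation), a
    rank-based per-cell module activity score, a Gamma-Poisson count simulator
    with planted differentially expressed gene modules, and benchmark metrics
    (AUROC, F1, Jaccard module recovery).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
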