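Package: clonetrace
Title: Clone Calling and Lineage-Coupling Analysis for Lineage-Barcoded
    Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clonal fate mapping with heritable lineage barcodes
    read out by single-cell RNA sequencing. Covers the full path from raw
    barcode evidence to biological statements: extraction of lineage
    barcodes from reads, read- and UMI-support filtering of cell-UMI-barcode
    triples, construction of the sparse cell-by-barcode incidence matrix,
    clone assignment by average-linkage clustering of Jaccard similarities,
    permutation-null lineage-coupling z-scores and their correlation
    structure, clone-level fate-composition summaries (restricted versus
    mixed clones, exclusive fate classification, intersection tables), and
    expression-side statistics (log-normalization, a scrambled-normalized
    PCA-distance stability statistic, and binned-control gene-set module
    scores). A synthetic-data generator with known clonal ground truth,
    modeled on a dual-progenitor cortical lineage-tracing experiment,
    provides oracles for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    ape,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
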