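Package: txglobals
Title: Global Transcriptome Properties Across Cell Types
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of global transcriptome properties from RNA-seq
    expression tables: counts of expressed genes across FPKM thresholds,
    the ratio of expressed transcripts per gene (a proxy for alternative
    splicing activity), upper-quartile normalization, replicate-correlation
    quality control, hierarchical clustering of cell types with uncentered
    Pearson correlation and centroid linkage, permutation tests for
    two-group differences in threshold curves, and summary filtering of
    differential-expression results. Includes a calibrated synthetic-data
    generator emulating multi-cell-type, replicated FPKM datasets so the
    full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    jsonlite
biocViews: Transcriptomics, RNASeq, GeneExpression, AlternativeSplicing,
    Clustering, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
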