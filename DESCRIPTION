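Package: maldr
Title: Monotone Alignment Depth Ratio Filtering for Age-Related Expression
    Trends
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects genes whose smoothed per-base alignment depth increases
    or decreases monotonically across ordered donor age groups in bulk
    RNA-seq of cultured dermal fibroblasts. Implements the MALDR filter
    (Monotone ALignment Depth Ratio): splice-junction (gap-site) counting
    from gapped alignments, a negative-binomial quasi-likelihood two-group
    pre-filter with Benjamini-Hochberg correction, intron and low-coverage
    restriction of gene regions, loess smoothing of group-mean depth, and
    the adjacent-group ratio test. Supporting stages include CPM summaries,
    correlation-set discovery by exact maximum-clique search, 6-mer spectrum
    sample QC, and a synthetic-data generator that reproduces the cohort
    structure the method assumes (27 donors, two body sites, three age
    groups) so every stage is testable without external data.
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
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    GenomicAlignments,
    jsonlite
biocViews: RNASeq, GeneExpression, Coverage, AlternativeSplicing,
    DifferentialExpression, QualityControl
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
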