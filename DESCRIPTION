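Package: maternalWnt
Title: Direct Maternal Wnt/Beta-Catenin Target Gene Calling from Staged
    Perturbation Transcriptomics and ChIP Peak Sets
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative identification of two classes of direct maternal
    Wnt/beta-catenin target genes in early vertebrate embryos. Combines
    rescue-gated negative-binomial differential expression from
    knockdown/rescue count experiments, surge-onset classification of staged
    transcripts-per-embryo time courses, stage-wise beta-catenin peak
    partitioning, Foxh1 co-binding context analysis with permutation nulls,
    ZOOPS de novo motif discovery on peak sequences, and a coherent
    feedforward epistasis test. A synthetic-study generator with known
    ground-truth labels makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
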