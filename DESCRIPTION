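Package: panstruct
Title: Population Structure Aggregation and Pan-Genome Statistics for Asian Rice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reimplements, at desk scale, the computational analyses behind a
    platinum-standard rice pan-genome resource: an EM estimator for the
    admixture model, label-switching alignment and aggregation of ensembles of
    Q matrices into subpopulation modes, membership classification with the
    0.65 rule and within-major-group admixed calls, identity-by-state
    distances with principal-coordinate representative selection, assembly
    summary statistics including an adjusted BUSCO gene-space correction,
    k-mer spectrum genome-size estimation, and pairwise structural-variation
    quantification via pseudo-read fragmentation with a toy-scale anchor
    chaining detector. Includes seeded synthetic-data generators so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    clue,
    data.table,
    stringi,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
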