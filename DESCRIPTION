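Package: bowerbrain
Title: Cell-Population Profiling of Bower-Building Behavior in Cichlids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking a recently evolved social behavior
    (castle-building in Lake Malawi cichlids) to brain cell populations.
    Implements depth-map bower detection and the Bower Activity Index,
    anchor-based discovery of immediate-early-gene-like genes and per-nucleus
    activity scores, a multi-model significance framework (beta-binomial and
    negative-binomial mixed models with harmonic-mean-p combination and a dual
    significance rule), expression-matched permutation gene-set enrichment,
    Weir-Cockerham windowed F_ST with dual-contrast intersection and estrogen
    response element scanning, and co-expression module discovery by
    partitioning around medoids over signed adjacency. A synthetic-data module
    generates all inputs with the statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    SingleCellExperiment,
    Biostrings,
    glmmTMB,
    lme4,
    cluster,
    vcfR,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'behavior.R'
    'bowerbrain-package.R'
    'coexpression.R'
    'competition.R'
    'core_io.R'
    'divergence.R'
    'enrichment.R'
    'iegscore.R'
    'syndata.R'
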