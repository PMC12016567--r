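Package: tadreorg
Title: TAD Reorganization and CTCF-Mediated Enhancer-Gene Rewiring from
    Two-Condition Hi-C, ChIP-seq, ATAC-seq and RNA-seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates binned Hi-C contact maps, CTCF and ATAC peak sets,
    and gene-level RNA-seq counts from two conditions (for example normal
    versus tumor cells) to identify genes whose expression change co-occurs
    with CTCF-mediated alterations of topologically associating domain
    (TAD) boundaries. Provides directionality-index TAD and boundary
    calling, A/B compartment eigenvector analysis, binomial significant
    cis/trans interaction calling with equal-occupancy distance strata,
    TMM/RPKM expression filtering and differential-expression calling, TAD
    reorganization typing (fusion, separation, shift), and a classifier
    that labels candidate enhancer-gene pairs under an intra-TAD (loop
    alteration) or inter-TAD (TAD reorganization) model. A seeded
    synthetic-data generator plants TAD reorganization events, matched
    CTCF/ATAC peaks, and expression truth so that every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    edgeR,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
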