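Package: tilearray
Title: Strand-Specific Differential Expression from High-Density Tiling
    Microarrays
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds custom chip description files (CDFs) for tiling and
    expression microarrays by filtering probe sequences and mapping them
    exactly to a reference genome with a Karp-Rabin rolling-hash search,
    quantifies probeset-level differential expression with robust
    multiarray averaging (convolution background adjustment, quantile
    normalization, median-polish summarization), and detects and
    quantifies strand-specific differentially transcribed regions from
    the probe-level differential signal with a cluster-and-fuse
    segmentation algorithm. Ships seeded simulators for genomes,
    annotations, probe designs and intensity matrices so the complete
    pipeline can be exercised against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    limma,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
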