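Package: retropop
Title: Population Analysis of LTR Retrotransposon Copies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification, dating and population analysis of full-length
    long-terminal-repeat (LTR) retrotransposon copies in chromosome-scale
    assemblies. Provides an affine-gap local/global pairwise aligner with a
    deterministic traceback, consensus-driven discovery of full-length
    elements and solo-LTRs (paired LTR hits at a family-specific distance,
    coding-sequence screen, target-site-duplication detection,
    size-distribution trimming), per-copy insertion dating from LTR-LTR
    divergence under a Kimura two-parameter clock, sub-family divergence
    dating from four-fold degenerate synonymous sites, a
    copy-by-consensus-position variant matrix with VCF export, PCA-based
    sub-family classification, and descriptive population summaries
    (chromosomal bins, activity-through-time tables, introgression-segment
    signatures). Includes a synthetic-genome simulator that plants
    retrotransposon populations with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    mgcv,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    cluster,
    jsonlite
Config/testthat/edition: 3
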