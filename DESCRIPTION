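Package: orthoscore
Title: Single-Copy Ortholog Completeness Assessment for Genomes, Gene Sets, and Transcriptomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the completeness and redundancy of genome assemblies,
    annotated gene sets, and transcriptomes from the recovery of lineage-specific
    universal single-copy ortholog markers. Provides a marker-dataset model with
    per-marker bit-score and length cutoffs, a self-contained position-specific
    profile search with exact Viterbi and Forward semantics, six-frame ORF
    extraction with automatic genetic-code selection by coding density, a
    two-pass rescue search for markers missed at default sensitivity,
    Complete/Duplicated/Fragmented/Missing classification with the canonical
    one-line score string, automatic lineage-dataset selection by greedy descent
    over a dataset hierarchy, batch assessment, a gene-depletion benchmark with
    false-positive/false-negative accounting, and a synthetic-lineage simulator
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    withr,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
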