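Package: chipglyco
Title: Promoter Peak Annotation, Degenerate Motif Matching and Lectin-Array Glycomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for the computational chain linking transcription-factor
    ChIP-seq peaks to downstream glyco-phenotypes: classification of peaks into
    promoter (Up2k), Down2k, exon, intron and intergenic regions with dual-control
    fold-enrichment filtering and peak-set intersection; degenerate consensus-motif
    parsing, reverse complementation and both-strand scanning with exact/partial
    match classification; the lectin-microarray normalization and differential
    glycan-calling protocol (background subtraction, effectiveness filtering,
    per-block global-median normalization, nine-block aggregation, paired t-tests);
    and the standard quantification formulas (2^-ddCt relative expression,
    ChIP-qPCR fold over IgG, dual-luciferase normalization). Includes seeded
    synthetic-data generators with planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    BiocGenerics,
    knitr
Config/testthat/edition: 3
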