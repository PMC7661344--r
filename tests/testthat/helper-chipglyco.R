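# Independent oracles and fixture builders used across the suite.

# Gene-model tibble from explicit fields; exons default to the full body.
make_gene <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                      start, end, exons = NULL) {
  if (is.null(exons)) exons <- tibble::tibble(start = start, end = end)
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = start, end = end,
    tss = if (strand == "+") start else end,
    tes = if (strand == "+") end else start,
    exons = list(exons)
  )
}

# Brute-force per-position region classification: scans every gene's
# features with plain arithmetic, independent of the GRanges index.
oracle_classify_position <- function(genes, chrom, pos, flank = 2000) {
  best <- 5L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != chrom) next
    tss <- if (g$strand == "+") g$start else g$end
    tes <- if (g$strand == "+") g$end else g$start
    up <- if (g$strand == "+") c(tss - flank, tss - 1) else c(tss + 1, tss + flank)
    dn <- if (g$strand == "+") c(tes + 1, tes + flank) else c(tes - flank, tes - 1)
    if (pos >= up[1] && pos <= up[2]) best <- min(best, 1L)
    if (pos >= dn[1] && pos <= dn[2]) best <- min(best, 2L)
    ex <- g$exons[[1]]
    if (any(pos >= ex$start & pos <= ex$end)) {
      best <- min(best, 3L)
    } else if (pos >= g$start && pos <= g$end) {
      best <- min(best, 4L)
    }
  }
  region_classes()[best]
}

# Degenerate pattern -> IUPAC ambiguity string.
pattern_to_iupac <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  keys <- vapply(map, function(v)
    paste(sort(strsplit(v, "")[[1]]), collapse = ""), character(1))
  paste(vapply(pattern$positions, function(set) {
    key <- paste(sort(strsplit(set, "")[[1]]), collapse = "")
    names(map)[match(key, keys)]
  }, character(1)), collapse = "")
}

# Independent motif-scan oracle via Biostrings ambiguity matching.
oracle_scan <- function(seq, pattern, both_strands = TRUE) {
  subj <- Biostrings::DNAString(seq)
  iu <- pattern_to_iupac(pattern)
  f <- Biostrings::matchPattern(iu, subj, fixed = FALSE)
  out <- tibble::tibble(offset = BiocGenerics::start(f) - 1L, strand = "+")
  if (both_strands) {
    iur <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(iu)))
    r <- Biostrings::matchPattern(iur, subj, fixed = FALSE)
    out <- dplyr::bind_rows(
      out, tibble::tibble(offset = BiocGenerics::start(r) - 1L, strand = "-"))
  }
  dplyr::arrange(out, offset, strand)
}

# Random bracket-notation pattern text of the given length.
random_pattern_text <- function(len) {
  paste(vapply(seq_len(len), function(i) {
    k <- sample(c(1, 1, 1, 2, 3, 4), 1)
    if (k == 4 && runif(1) < 0.5) return("x")
    b <- sample(c("A", "C", "G", "T"), k)
    if (k == 1) b else paste0("[", paste(b, collapse = ""), "]")
  }, character(1)), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
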