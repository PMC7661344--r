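#' Write gene models to GFF3
#'
#' Emits one `gene` feature per gene and `exon` children linked by
#' `Parent`, via rtracklayer.
#'
#' @param genes Gene-model tibble (see [sim_gene_models()]).
#' @param path Output file path.
#' @export
write_genes_gff3 <- function(genes, path) {
  .validate_genes(genes)
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gene_gr)$type <- "gene"
  S4Vectors::mcols(gene_gr)$ID <- genes$gene_id
  ex <- tidyr::unnest(select(genes, "gene_id", "chrom", "strand", "exons"),
                      "exons")
  exon_gr <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start, ex$end), strand = ex$strand
  )
  S4Vectors::mcols(exon_gr)$type <- "exon"
  S4Vectors::mcols(exon_gr)$Parent <- ex$gene_id
  rtracklayer::export(c(gene_gr, exon_gr), path, format = "gff3")
  invisible(path)
}

#' Write gene models to BED6
#'
#' One line per gene span (name = gene id, score 0, strand); exon
#' structure is not representable in BED6 and is dropped.
#'
#' @inheritParams write_genes_gff3
#' @export
write_genes_bed6 <- function(genes, path) {
  .validate_genes(genes)
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$name <- genes$gene_id
  S4Vectors::mcols(gr)$score <- 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene models from GFF3 or BED6
#'
#' GFF3 files must carry `gene` features with `ID` and `exon` features
#' with `Parent`; BED6 genes become single-exon genes spanning the
#' interval. Coordinates are returned 1-based closed (BED's 0-based
#' half-open convention is converted on import by rtracklayer).
#'
#' @param path A `.gff3`/`.gff` or `.bed` file.
#' @return A gene-model tibble (see [sim_gene_models()]).
#' @export
read_gene_models <- function(path) {
  is_bed <- grepl("\\.bed$", path, ignore.case = TRUE)
  gr <- rtracklayer::import(path)
  if (is_bed) {
    tbl <- tibble(
      gene_id = S4Vectors::mcols(gr)$name,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr)
    )
    return(tbl |>
             mutate(
               tss = if_else(.data$strand == "+", .data$start, .data$end),
               tes = if_else(.data$strand == "+", .data$end, .data$start),
               exons = purrr::map2(.data$start, .data$end,
                                   ~ tibble(start = .x, end = .y))
             ))
  }
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  genes <- tibble(
    gene_id = as.character(md$ID[is_gene]),
    chrom = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    strand = as.character(GenomicRanges::strand(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene]
  )
  ex_parent <- as.character(unlist(md$Parent[md$type == "exon"]))
  ex <- tibble(
    gene_id = ex_parent,
    start = GenomicRanges::start(gr)[md$type == "exon"],
    end = GenomicRanges::end(gr)[md$type == "exon"]
  )
  genes |>
    mutate(
      tss = if_else(.data$strand == "+", .data$start, .data$end),
      tes = if_else(.data$strand == "+", .data$end, .data$start),
      exons = purrr::map(.data$gene_id, function(g) {
        e <- filter(ex, .data$gene_id == g) |>
          select("start", "end") |>
          arrange(.data$start)
        if (nrow(e) == 0) {
          e <- tibble(start = genes$start[genes$gene_id == g],
                      end = genes$end[genes$gene_id == g])
        }
        e
      })
    )
}

#' Read or write a peak table as TSV
#'
#' Peaks are tab-separated with a header; a single-contrast table has
#' columns `peak_id, chrom, start, end, fold`, a dual-contrast table
#' `peak_id, chrom, start, end, fold_m1, fold_m2`. A raw-count table
#' (`treat_count`, `ctrl_count`, `treat_depth`, `ctrl_depth` columns)
#' has its `fold` computed on read via [fold_enrichment()].
#'
#' @param peaks Peak tibble.
#' @param path TSV path.
#' @param pseudocount Passed to [fold_enrichment()] for count tables.
#' @return `read_peaks_tsv()` returns a tibble; `write_peaks_tsv()`
#'   its path, invisibly.
#' @export
write_peaks_tsv <- function(peaks, path) {
  readr::write_tsv(peaks, path)
  invisible(path)
}

#' @rdname write_peaks_tsv
#' @export
read_peaks_tsv <- function(path, pseudocount = 1) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  counts <- c("treat_count", "ctrl_count", "treat_depth", "ctrl_depth")
  if (all(counts %in% names(tbl)) && !"fold" %in% names(tbl)) {
    tbl <- mutate(tbl, fold = fold_enrichment(
      .data$treat_count, .data$ctrl_count,
      .data$treat_depth, .data$ctrl_depth, pseudocount
    ))
  }
  tbl
}

#' Read or write sequences as FASTA
#'
#' Thin wrappers over Biostrings between FASTA files and
#' `tibble(seq_id, sequence)`.
#'
#' @param seqs Tibble with `seq_id` and `sequence`.
#' @param path FASTA path.
#' @export
write_fasta_tbl <- function(seqs, path) {
  seqs <- .as_seq_tbl(seqs)
  xs <- Biostrings::DNAStringSet(setNames(seqs$sequence, seqs$seq_id))
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' @rdname write_fasta_tbl
#' @export
read_fasta_tbl <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  tibble(seq_id = names(xs), sequence = unname(as.character(xs)))
}

#' Read or write lectin-array spot grids as TSV
#'
#' @param spots Spot tibble (`condition`, `slide`, `block`, `lectin`,
#'   `foreground`, `background`).
#' @param path TSV path.
#' @export
write_spots_tsv <- function(spots, path) {
  readr::write_tsv(spots, path)
  invisible(path)
}

#' @rdname write_spots_tsv
#' @export
read_spots_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("slide", "block", "lectin", "foreground", "background")
  if (!all(need %in% names(tbl))) {
    abort(sprintf("Spot TSV must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  tbl
}

#' Read or write Ct tables as TSV
#'
#' @param ct Ct tibble (`condition`, `gene_id`, `role`, `replicate`,
#'   `ct`).
#' @param path TSV path.
#' @export
write_ct_tsv <- function(ct, path) {
  readr::write_tsv(ct, path)
  invisible(path)
}

#' @rdname write_ct_tsv
#' @export
read_ct_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write or read a planted-truth sidecar as JSON
#'
#' Serializes the truth tables of the simulators (data frames and
#' scalars) so a simulated dataset can be re-validated later.
#'
#' @param truth A list or tibble of planted truth.
#' @param path JSON path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(out)) as_tibble(out)
  else purrr::map(out, function(x) if (is.data.frame(x)) as_tibble(x) else x)
}
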