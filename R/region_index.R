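#' Genomic region classes
#'
#' The five region classes used to annotate peaks, in decreasing
#' assignment priority: `UP2K` (the 2,000 bp strictly upstream of a
#' gene's TSS on its strand), `DOWN2K` (the 2,000 bp strictly downstream
#' of the transcription end site), `EXON`, `INTRON` and `INTERGENIC`.
#' When a position lies in regions of multiple genes the
#' highest-priority class wins.
#'
#' @export
region_classes <- function() c("UP2K", "DOWN2K", "EXON", "INTRON", "INTERGENIC")

.validate_genes <- function(genes, chrom_lengths = NULL) {
  need <- c("gene_id", "chrom", "strand", "start", "end", "exons")
  if (!all(need %in% names(genes))) {
    abort(sprintf("genes must have columns: %s", paste(need, collapse = ", ")))
  }
  if (any(!genes$strand %in% c("+", "-"))) abort("strand must be '+' or '-'.")
  if (any(genes$start > genes$end)) abort("gene start must be <= end.")
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (!is.data.frame(ex) || nrow(ex) < 1) {
      abort(sprintf("gene '%s' must have at least one exon.", genes$gene_id[i]))
    }
    if (any(ex$start > ex$end) ||
        any(ex$start < genes$start[i]) || any(ex$end > genes$end[i])) {
      abort(sprintf("exons of gene '%s' outside gene body.", genes$gene_id[i]))
    }
    o <- order(ex$start)
    if (any(ex$end[o][-nrow(ex)] >= ex$start[o][-1])) {
      abort(sprintf("exons of gene '%s' overlap.", genes$gene_id[i]))
    }
  }
  if (!is.null(chrom_lengths)) {
    bad <- !genes$chrom %in% names(chrom_lengths)
    if (any(bad)) {
      abort(sprintf("gene '%s' on unknown chromosome '%s'.",
                    genes$gene_id[bad][1], genes$chrom[bad][1]))
    }
    lim <- unname(chrom_lengths[genes$chrom])
    if (any(genes$start < 1 | genes$end > lim)) {
      abort("gene outside chromosome bounds.")
    }
  }
  invisible(genes)
}

# TSS/TES from the gene span and strand (1-based closed coordinates).
.gene_anchors <- function(genes) {
  mutate(genes,
         tss = if_else(.data$strand == "+", .data$start, .data$end),
         tes = if_else(.data$strand == "+", .data$end, .data$start))
}

#' Build a queryable region index from gene models
#'
#' Derives, for a set of stranded gene models, the Up2k, Down2k, exon
#' and intron intervals (1-based closed, clipped to chromosome bounds);
#' positions covered by none of these are intergenic. The index resolves
#' multi-gene overlaps with the priority
#' UP2K > DOWN2K > EXON > INTRON > INTERGENIC.
#'
#' @param genes Gene-model tibble with columns `gene_id`, `chrom`,
#'   `strand`, `start`, `end` and an `exons` list-column of
#'   `tibble(start, end)` (closed intervals inside the gene body).
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param flank Promoter/downstream flank size in bp (default 2000).
#' @return A `region_index` object.
#' @export
region_map <- function(genes, chrom_lengths, flank = 2000) {
  stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)),
            all(chrom_lengths > 0))
  .validate_genes(genes, chrom_lengths)
  genes <- .gene_anchors(genes)

  clip <- function(s, e, chrom) {
    lim <- unname(chrom_lengths[chrom])
    tibble(start = pmax(1, s), end = pmin(lim, e)) |>
      mutate(ok = .data$start <= .data$end)
  }

  rows <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    up <- if (g$strand == "+") c(g$tss - flank, g$tss - 1)
          else c(g$tss + 1, g$tss + flank)
    dn <- if (g$strand == "+") c(g$tes + 1, g$tes + flank)
          else c(g$tes - flank, g$tes - 1)
    ex <- g$exons[[1]]
    exon_r <- IRanges::IRanges(ex$start, ex$end)
    intron_r <- IRanges::gaps(exon_r, start = g$start, end = g$end)
    out <- list(
      tibble(class = "UP2K", start = up[1], end = up[2]),
      tibble(class = "DOWN2K", start = dn[1], end = dn[2]),
      tibble(class = "EXON", start = ex$start, end = ex$end)
    )
    if (length(intron_r) > 0) {
      out <- c(out, list(tibble(class = "INTRON",
                                start = IRanges::start(intron_r),
                                end = IRanges::end(intron_r))))
    }
    bind_rows(out) |>
      mutate(gene_id = g$gene_id, chrom = g$chrom)
  })
  clipped <- clip(rows$start, rows$end, rows$chrom)
  rows$start <- clipped$start
  rows$end <- clipped$end
  rows <- rows[clipped$ok, , drop = FALSE]

  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(rows$start, rows$end),
    class = rows$class, gene_id = rows$gene_id
  )
  structure(
    list(regions = gr, chrom_lengths = chrom_lengths,
         genes = genes, flank = flank),
    class = "region_index"
  )
}

#' @export
print.region_index <- function(x, ...) {
  cat("<region_index> ", nrow(x$genes), " genes on ",
      length(x$chrom_lengths), " chromosomes; flank ", x$flank, " bp\n",
      sep = "")
  invisible(x)
}

#' Classify genomic positions
#'
#' Maps each (chrom, pos) to its region class under the index's
#' priority rule. Every position maps to exactly one class.
#'
#' @param index A `region_index`.
#' @param positions Tibble with columns `chrom` and `pos` (1-based).
#' @return The input tibble with a `region` column added.
#' @export
classify_positions <- function(index, positions) {
  stopifnot(inherits(index, "region_index"),
            all(c("chrom", "pos") %in% names(positions)))
  unknown <- setdiff(unique(positions$chrom), names(index$chrom_lengths))
  if (length(unknown)) {
    abort(sprintf("Unknown chromosome '%s' in positions.", unknown[1]))
  }
  q <- GenomicRanges::GRanges(positions$chrom,
                              IRanges::IRanges(positions$pos, positions$pos))
  hits <- GenomicRanges::findOverlaps(q, index$regions)
  prio <- match(S4Vectors::mcols(index$regions)$class, region_classes())
  cls <- rep("INTERGENIC", nrow(positions))
  if (length(hits)) {
    h <- tibble(qi = S4Vectors::queryHits(hits),
                p = prio[S4Vectors::subjectHits(hits)]) |>
      group_by(.data$qi) |>
      summarise(p = min(.data$p), .groups = "drop")
    cls[h$qi] <- region_classes()[h$p]
  }
  mutate(positions, region = cls)
}

#' Classify peaks by midpoint
#'
#' Assigns each peak the region class of its midpoint
#' (`floor((start + end) / 2)`), with multi-gene overlap resolved by
#' the priority UP2K > DOWN2K > EXON > INTRON > INTERGENIC. Midpoint
#' classification is deterministic and respects the genome partition.
#'
#' @param peaks Tibble with columns `peak_id`, `chrom`, `start`, `end`
#'   (1-based closed).
#' @param index A `region_index`.
#' @return The peak tibble with `midpoint` and `region` columns added.
#' @export
classify_peaks <- function(peaks, index) {
  need <- c("peak_id", "chrom", "start", "end")
  if (!all(need %in% names(peaks))) {
    abort(sprintf("peaks must have columns: %s", paste(need, collapse = ", ")))
  }
  if (nrow(peaks) == 0) return(mutate(peaks, midpoint = numeric(0), region = character(0)))
  if (any(peaks$start > peaks$end)) abort("peak start must be <= end.")
  mid <- floor((peaks$start + peaks$end) / 2)
  cls <- classify_positions(index, tibble(chrom = peaks$chrom, pos = mid))
  mutate(peaks, midpoint = mid, region = cls$region)
}

#' Tally peak classifications by region class
#'
#' @param classified Output of [classify_peaks()].
#' @return Tibble with one row per region class (all five classes
#'   always present): `region`, `n`, `fraction`.
#' @export
region_distribution <- function(classified) {
  stopifnot("region" %in% names(classified))
  tot <- nrow(classified)
  tibble(region = region_classes()) |>
    left_join(count(classified, .data$region), by = "region") |>
    mutate(n = if_else(is.na(.data$n), 0L, .data$n),
           fraction = if (tot > 0) .data$n / tot else 0)
}
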