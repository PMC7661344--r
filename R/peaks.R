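#' Depth-normalized fold enrichment
#'
#' Fold enrichment of a treatment count over a control count, each
#' normalized by its library depth, with a pseudocount added to both
#' counts to keep the ratio finite:
#' `((treat + pc) / treat_depth) / ((ctrl + pc) / ctrl_depth)`.
#'
#' @param treat_count,ctrl_count Read counts (>= 0); vectorized.
#' @param treat_depth,ctrl_depth Library depths (> 0).
#' @param pseudocount Added to both counts (default 1, >= 0).
#' @return Numeric vector of fold enrichments.
#' @examples
#' fold_enrichment(73, 10, 1e6, 1e6, pseudocount = 0) # 7.3
#' @export
fold_enrichment <- function(treat_count, ctrl_count,
                            treat_depth = 1, ctrl_depth = 1,
                            pseudocount = 1) {
  if (any(treat_depth <= 0) || any(ctrl_depth <= 0)) {
    abort("Library depths must be > 0.")
  }
  if (any(treat_count < 0) || any(ctrl_count < 0)) {
    abort("Counts must be >= 0.")
  }
  if (any(pseudocount < 0)) abort("pseudocount must be >= 0.")
  ((treat_count + pseudocount) / treat_depth) /
    ((ctrl_count + pseudocount) / ctrl_depth)
}

.validate_peaks <- function(peaks, fold_col = "fold") {
  need <- c("peak_id", "chrom", "start", "end", fold_col)
  if (!all(need %in% names(peaks))) {
    abort(sprintf("peak tibble must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  if (any(peaks$start > peaks$end)) abort("peak start must be <= end.")
  if (any(peaks[[fold_col]] < 0)) abort("fold enrichments must be >= 0.")
  invisible(peaks)
}

# Greedy 1:1 pairing of overlapping peaks: largest overlap first,
# ties broken by leftmost m1 start, then leftmost m2 start.
.pair_overlaps <- function(m1, m2, min_overlap) {
  if (nrow(m1) == 0 || nrow(m2) == 0) {
    return(tibble(m1_id = character(), m2_id = character(),
                  chrom = character(), overlap_bp = numeric()))
  }
  g1 <- GenomicRanges::GRanges(m1$chrom, IRanges::IRanges(m1$start, m1$end))
  g2 <- GenomicRanges::GRanges(m2$chrom, IRanges::IRanges(m2$start, m2$end))
  hits <- GenomicRanges::findOverlaps(g1, g2, minoverlap = min_overlap)
  if (length(hits) == 0) {
    return(tibble(m1_id = character(), m2_id = character(),
                  chrom = character(), overlap_bp = numeric()))
  }
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(m1$end[qi], m2$end[si]) - pmax(m1$start[qi], m2$start[si]) + 1
  cand <- tibble(qi = qi, si = si, overlap_bp = ov,
                 s1 = m1$start[qi], s2 = m2$start[si]) |>
    arrange(dplyr::desc(.data$overlap_bp), .data$s1, .data$s2)
  used1 <- rep(FALSE, nrow(m1))
  used2 <- rep(FALSE, nrow(m2))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    a <- cand$qi[i]; b <- cand$si[i]
    if (!used1[a] && !used2[b]) {
      keep[i] <- TRUE
      used1[a] <- TRUE
      used2[b] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  tibble(m1_id = m1$peak_id[cand$qi], m2_id = m2$peak_id[cand$si],
         chrom = m1$chrom[cand$qi], overlap_bp = cand$overlap_bp)
}

#' Filter two peak contrasts by fold enrichment and intersect them
#'
#' Applies the fold-enrichment cut-off to each contrast (M1 = ChIP vs
#' IgG; M2 = ChIP vs input), then pairs the surviving peaks across the
#' two sets: two peaks are common when they lie on the same chromosome
#' and overlap by at least `min_overlap` bp. Each peak joins at most one
#' pair; pairing is greedy by largest overlap, ties broken by leftmost
#' start, making the result deterministic and order-independent.
#'
#' @param m1,m2 Peak tibbles with columns `peak_id`, `chrom`, `start`,
#'   `end`, `fold` (1-based closed coordinates).
#' @param threshold Fold-enrichment cut-off (default 2).
#' @param min_overlap Minimum overlap in bp to call two peaks common
#'   (default 1).
#' @param strict If `TRUE` (default) a peak passes with fold strictly
#'   greater than `threshold` ("over 2-fold"); if `FALSE`, `>=` is used.
#' @return A `peak_comparison` object: list with `m1_pass`, `m2_pass`
#'   (filtered tibbles), `common` (tibble of paired ids with overlap),
#'   `per_chrom` (per-chromosome counts including zero rows) and the
#'   parameters used.
#' @export
filter_and_intersect <- function(m1, m2, threshold = 2, min_overlap = 1,
                                 strict = TRUE) {
  stopifnot(threshold > 0, min_overlap >= 1)
  .validate_peaks(m1)
  .validate_peaks(m2)
  pass <- function(x) {
    if (strict) filter(x, .data$fold > threshold)
    else filter(x, .data$fold >= threshold)
  }
  m1_pass <- pass(m1)
  m2_pass <- pass(m2)
  common <- .pair_overlaps(m1_pass, m2_pass, min_overlap)
  chroms <- sort(unique(c(m1$chrom, m2$chrom)))
  out <- structure(
    list(m1_pass = m1_pass, m2_pass = m2_pass, common = common,
         chroms = chroms, threshold = threshold,
         min_overlap = min_overlap, strict = strict),
    class = "peak_comparison"
  )
  out$per_chrom <- chromosome_distribution(out)
  out
}

#' Per-chromosome counts of filtered and common peaks
#'
#' @param comparison A `peak_comparison`.
#' @param chroms Optional chromosome universe; chromosomes with zero
#'   peaks are reported as 0, never omitted. Defaults to every
#'   chromosome seen in the input peak lists.
#' @return Tibble: `chrom`, `m1`, `m2`, `common`.
#' @export
chromosome_distribution <- function(comparison, chroms = NULL) {
  stopifnot(inherits(comparison, "peak_comparison"))
  if (is.null(chroms)) chroms <- comparison$chroms
  cnt <- function(x) {
    if (nrow(x) == 0) return(setNames(integer(0), character(0)))
    table(x$chrom)
  }
  c1 <- cnt(comparison$m1_pass)
  c2 <- cnt(comparison$m2_pass)
  cc <- cnt(comparison$common)
  tibble(
    chrom = chroms,
    m1 = as.integer(ifelse(is.na(c1[chroms]), 0, c1[chroms])),
    m2 = as.integer(ifelse(is.na(c2[chroms]), 0, c2[chroms])),
    common = as.integer(ifelse(is.na(cc[chroms]), 0, cc[chroms]))
  )
}

#' @export
print.peak_comparison <- function(x, ...) {
  cat("<peak_comparison> threshold ",
      if (x$strict) "> " else ">= ", x$threshold,
      ": |M1| = ", nrow(x$m1_pass),
      ", |M2| = ", nrow(x$m2_pass),
      ", common = ", nrow(x$common), "\n", sep = "")
  invisible(x)
}

#' @describeIn filter_and_intersect Tidy the common-peak pairs.
#' @param x A `peak_comparison`.
#' @param ... Unused.
#' @method tidy peak_comparison
#' @export
tidy.peak_comparison <- function(x, ...) {
  as_tibble(x$common)
}

#' @describeIn filter_and_intersect One-row summary of the comparison.
#' @method glance peak_comparison
#' @export
glance.peak_comparison <- function(x, ...) {
  tibble(
    n_m1_pass = nrow(x$m1_pass),
    n_m2_pass = nrow(x$m2_pass),
    n_common = nrow(x$common),
    threshold = x$threshold,
    strict = x$strict,
    min_overlap = x$min_overlap
  )
}
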