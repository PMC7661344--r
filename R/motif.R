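#' Parse a degenerate consensus pattern
#'
#' Parses bracket-notation consensus motifs such as
#' `"CCTC[AT][GC]CC[TA]CC[CT]"`: a literal base matches itself, a bracket
#' group matches any base inside it, and `x` is a wildcard matching any
#' base (including `N`). Matching is case-insensitive.
#'
#' @param text A single pattern string over `{A,C,G,T,x,[,]}`.
#' @param id Optional pattern identifier carried in reports.
#' @return A `degenerate_pattern`: a list with `positions` (character
#'   vector, each element the sorted allowed bases at that position;
#'   `"ACGT"` for a wildcard), `wildcard` (logical vector) and
#'   `source_text`.
#' @examples
#' p <- parse_pattern("CCTC[AT][GC]CC[TA]CC[CT]")
#' pattern_length(p) # 12
#' @export
parse_pattern <- function(text, id = NULL) {
  stopifnot(is.character(text), length(text) == 1, nzchar(text))
  chars <- strsplit(toupper(text), "", fixed = TRUE)[[1]]
  positions <- character(0)
  wildcard <- logical(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("A", "C", "G", "T")) {
      positions <- c(positions, ch)
      wildcard <- c(wildcard, FALSE)
      i <- i + 1L
    } else if (ch == "X") {
      positions <- c(positions, "ACGT")
      wildcard <- c(wildcard, TRUE)
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      grp <- character(0)
      while (j <= n && chars[j] != "]") {
        if (!chars[j] %in% c("A", "C", "G", "T")) {
          abort(sprintf(
            "Illegal character '%s' inside bracket group at offset %d in '%s'",
            chars[j], j - 1L, text
          ))
        }
        grp <- c(grp, chars[j])
        j <- j + 1L
      }
      if (j > n) {
        abort(sprintf("Unbalanced bracket at offset %d in '%s'", i - 1L, text))
      }
      if (length(grp) == 0) {
        abort(sprintf("Empty bracket group at offset %d in '%s'", i - 1L, text))
      }
      grp <- unique(grp)
      positions <- c(positions, paste(grp, collapse = ""))
      wildcard <- c(wildcard, all(c("A", "C", "G", "T") %in% grp))
      i <- j + 1L
    } else {
      abort(sprintf("Illegal character '%s' at offset %d in '%s'",
                    ch, i - 1L, text))
    }
  }
  structure(
    list(positions = positions, wildcard = wildcard, source_text = text),
    class = "degenerate_pattern"
  )
}

#' @export
print.degenerate_pattern <- function(x, ...) {
  cat("<degenerate_pattern> ", render_pattern(x),
      " (", length(x$positions), " positions)\n", sep = "")
  invisible(x)
}

#' Number of positions in a degenerate pattern
#' @param pattern A `degenerate_pattern`.
#' @export
pattern_length <- function(pattern) {
  stopifnot(inherits(pattern, "degenerate_pattern"))
  length(pattern$positions)
}

#' Render a degenerate pattern back to bracket notation
#'
#' Wildcard positions render as `x`, single bases as themselves and
#' other base sets as bracket groups; `parse_pattern(render_pattern(p))`
#' reproduces `p`'s position sets.
#'
#' @inheritParams pattern_length
#' @return A pattern string.
#' @export
render_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "degenerate_pattern"))
  paste(vapply(seq_along(pattern$positions), function(i) {
    p <- pattern$positions[i]
    if (pattern$wildcard[i]) "x"
    else if (nchar(p) == 1) p
    else paste0("[", p, "]")
  }, character(1)), collapse = "")
}

#' Reverse complement of a degenerate pattern
#'
#' Reverses the position order and complements every base set
#' (A<->T, C<->G); wildcards map to wildcards. The operation is an
#' involution: `reverse_complement(reverse_complement(p))` equals `p`.
#'
#' @inheritParams pattern_length
#' @return A `degenerate_pattern`.
#' @examples
#' render_pattern(reverse_complement(parse_pattern("CCTC[AT][GC]CC[TA]CC[CT]")))
#' # "[GA]GG[AT]GG[CG][TA]GAGG"
#' @export
reverse_complement <- function(pattern) {
  stopifnot(inherits(pattern, "degenerate_pattern"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pos <- rev(vapply(pattern$positions, function(p) {
    bases <- strsplit(p, "", fixed = TRUE)[[1]]
    paste(unname(comp[bases]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
  wc <- rev(pattern$wildcard)
  out <- structure(
    list(positions = pos, wildcard = wc, source_text = NA_character_),
    class = "degenerate_pattern"
  )
  out$source_text <- render_pattern(out)
  out
}

# Per-position match matrix helper: logical vector over offsets 1..n-m+1
# for whether pattern position i matches target; N satisfies only wildcards.
.match_offsets <- function(chars, pattern) {
  m <- length(pattern$positions)
  n <- length(chars)
  if (m > n) return(logical(0))
  k <- n - m + 1L
  ok <- rep(TRUE, k)
  for (i in seq_len(m)) {
    window <- chars[i:(i + k - 1L)]
    if (pattern$wildcard[i]) next
    allowed <- strsplit(pattern$positions[i], "", fixed = TRUE)[[1]]
    ok <- ok & window %in% allowed
  }
  ok
}

.as_pattern_list <- function(patterns) {
  if (inherits(patterns, "degenerate_pattern")) patterns <- list(patterns)
  if (is.character(patterns)) patterns <- lapply(patterns, parse_pattern)
  if (!is.list(patterns) || length(patterns) == 0 ||
      !all(vapply(patterns, inherits, logical(1), "degenerate_pattern"))) {
    abort("patterns must be a non-empty list of degenerate_pattern objects, pattern strings, or one pattern.")
  }
  if (is.null(names(patterns)) || any(!nzchar(names(patterns)))) {
    names(patterns) <- paste0("motif", seq_along(patterns))
  }
  patterns
}

.empty_matches <- function() {
  tibble(target_id = character(), pattern_id = character(),
         offset = integer(), strand = character(), length = integer(),
         match_type = character(), matched_span = character())
}

#' Scan sequences for degenerate-motif matches
#'
#' Tests every window of pattern length against each pattern; with
#' `both_strands` the reverse-complement pattern is also scanned and hits
#' are reported on strand `-` at their position in the forward sequence.
#' Offsets are 0-based. `N` in a target never satisfies a non-wildcard
#' position. A pattern longer than a target yields no matches.
#'
#' @param seqs A tibble with columns `seq_id` and `sequence`, a named
#'   character vector, or a single (optionally named) sequence string.
#' @param patterns One `degenerate_pattern` / pattern string, or a
#'   (named) list/vector of them.
#' @param both_strands Scan the reverse-complement pattern too.
#' @return A tibble of full-length matches sorted by
#'   (`target_id`, `pattern_id`, `offset`, `strand`): columns
#'   `target_id`, `pattern_id`, `offset` (0-based), `strand`, `length`,
#'   `match_type` (`"EXACT"`) and `matched_span` (forward-strand target
#'   substring).
#' @examples
#' scan_motif("GGCAGGCAAAGG", "[GA][GA][GC][AT]GG[CG]xxAGG")
#' @export
scan_motif <- function(seqs, patterns, both_strands = TRUE) {
  seqs <- .as_seq_tbl(seqs)
  patterns <- .as_pattern_list(patterns)
  res <- purrr::map_dfr(seq_len(nrow(seqs)), function(si) {
    chars <- strsplit(toupper(seqs$sequence[si]), "", fixed = TRUE)[[1]]
    purrr::map_dfr(names(patterns), function(pid) {
      pat <- patterns[[pid]]
      m <- pattern_length(pat)
      hits_f <- which(.match_offsets(chars, pat))
      rows <- list()
      if (length(hits_f)) {
        rows$f <- tibble(
          target_id = seqs$seq_id[si], pattern_id = pid,
          offset = hits_f - 1L, strand = "+", length = m,
          match_type = "EXACT",
          matched_span = vapply(hits_f, function(o)
            paste(chars[o:(o + m - 1L)], collapse = ""), character(1))
        )
      }
      if (both_strands) {
        hits_r <- which(.match_offsets(chars, reverse_complement(pat)))
        if (length(hits_r)) {
          rows$r <- tibble(
            target_id = seqs$seq_id[si], pattern_id = pid,
            offset = hits_r - 1L, strand = "-", length = m,
            match_type = "EXACT",
            matched_span = vapply(hits_r, function(o)
              paste(chars[o:(o + m - 1L)], collapse = ""), character(1))
          )
        }
      }
      bind_rows(rows)
    })
  })
  if (nrow(res) == 0) return(.empty_matches())
  arrange(res, .data$target_id, .data$pattern_id, .data$offset, .data$strand)
}

.as_seq_tbl <- function(seqs) {
  if (is.data.frame(seqs)) {
    if (!all(c("seq_id", "sequence") %in% names(seqs))) {
      abort("Sequence tibble needs columns seq_id and sequence.")
    }
    return(as_tibble(seqs[, c("seq_id", "sequence")]))
  }
  if (is.character(seqs)) {
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    return(tibble(seq_id = ids, sequence = unname(seqs)))
  }
  abort("seqs must be a tibble(seq_id, sequence) or a character vector.")
}

# Longest contiguous run of matching pattern positions when the pattern
# is slid across the target at every alignment (overhangs allowed down
# to run_min overlapping positions). Returns the best run per alignment
# family as a one-row list or NULL.
.best_partial <- function(chars, pattern, strand, run_min) {
  m <- length(pattern$positions)
  n <- length(chars)
  best <- NULL
  allowed <- lapply(pattern$positions, function(p)
    strsplit(p, "", fixed = TRUE)[[1]])
  for (off in seq.int(-(m - run_min), n - run_min)) {
    # pattern position i aligns to target index off + i (1-based target)
    i_lo <- max(1L, 1L - off)
    i_hi <- min(m, n - off)
    if (i_hi - i_lo + 1L < run_min) next
    idx <- i_lo:i_hi
    okv <- vapply(idx, function(i) {
      b <- chars[off + i]
      pattern$wildcard[i] || b %in% allowed[[i]]
    }, logical(1))
    r <- rle(okv)
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= 1L)
    for (k in runs) {
      len <- r$lengths[k]
      t_start <- off + idx[starts[k]]   # 1-based target position
      cand <- list(run = len, offset = t_start - 1L, strand = strand)
      if (is.null(best) ||
          len > best$run ||
          (len == best$run && cand$offset < best$offset) ||
          (len == best$run && cand$offset == best$offset &&
           strand == "+" && best$strand == "-")) {
        best <- cand
      }
    }
  }
  best
}

#' Classify a sequence against a motif set
#'
#' Decides whether a target sequence carries an `EXACT` full-length match
#' to any pattern (either strand), failing that a `PARTIAL` match — a
#' contiguous run of at least `partial_min` consecutive pattern positions
#' agreeing with the target at some alignment — and otherwise `NONE`.
#' The best match is reported with a deterministic tie-break: longest
#' run, then smallest offset, then `+` strand.
#'
#' @inheritParams scan_motif
#' @param partial_min Minimum contiguous run (pattern positions) for a
#'   PARTIAL call; default 7.
#' @return A tibble, one row per target: `target_id`, `match_type`
#'   (`EXACT`/`PARTIAL`/`NONE`), `pattern_id`, `offset` (0-based),
#'   `strand`, `length` (matched run length) and `matched_span`.
#' @export
classify_sequence <- function(seqs, patterns, partial_min = 7,
                              both_strands = TRUE) {
  stopifnot(partial_min >= 1)
  seqs <- .as_seq_tbl(seqs)
  patterns <- .as_pattern_list(patterns)
  purrr::map_dfr(seq_len(nrow(seqs)), function(si) {
    chars <- strsplit(toupper(seqs$sequence[si]), "", fixed = TRUE)[[1]]
    exact <- scan_motif(seqs[si, ], patterns, both_strands = both_strands)
    if (nrow(exact) > 0) {
      best <- exact |>
        arrange(dplyr::desc(.data$length), .data$offset, .data$strand) |>
        dplyr::slice(1)
      return(mutate(best, match_type = "EXACT") |>
               select("target_id", "match_type", "pattern_id", "offset",
                      "strand", "length", "matched_span"))
    }
    best <- NULL
    best_pid <- NA_character_
    for (pid in names(patterns)) {
      variants <- list(`+` = patterns[[pid]])
      if (both_strands) variants$`-` <- reverse_complement(patterns[[pid]])
      for (strand in names(variants)) {
        cand <- .best_partial(chars, variants[[strand]], strand, partial_min)
        if (!is.null(cand) &&
            (is.null(best) || cand$run > best$run ||
             (cand$run == best$run && cand$offset < best$offset) ||
             (cand$run == best$run && cand$offset == best$offset &&
              strand == "+" && best$strand == "-"))) {
          best <- cand
          best_pid <- pid
        }
      }
    }
    if (is.null(best) || best$run < partial_min) {
      return(tibble(target_id = seqs$seq_id[si], match_type = "NONE",
                    pattern_id = NA_character_, offset = NA_integer_,
                    strand = NA_character_, length = NA_integer_,
                    matched_span = NA_character_))
    }
    tibble(
      target_id = seqs$seq_id[si], match_type = "PARTIAL",
      pattern_id = best_pid, offset = best$offset, strand = best$strand,
      length = best$run,
      matched_span = paste(
        chars[(best$offset + 1L):(best$offset + best$run)], collapse = "")
    )
  })
}

#' The consensus motif configuration shipped with the package
#'
#' Returns the configured degenerate consensus motifs as a named list of
#' patterns. Only motif 1 (and its published looser reverse-complement
#' form, usable as a pattern in its own right) is distributed; the
#' remaining motifs of the original six-motif set were shown only as
#' figure images and must be supplied by the user via `extra`.
#'
#' @param extra Optional named character vector of additional
#'   bracket-notation patterns to append.
#' @return Named list of `degenerate_pattern` objects.
#' @export
consensus_motifs <- function(extra = NULL) {
  path <- system.file("extdata", "consensus_motifs.tsv",
                      package = "chipglyco", mustWork = TRUE)
  cfg <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  pats <- purrr::map(cfg$pattern, parse_pattern)
  names(pats) <- cfg$motif_id
  if (!is.null(extra)) {
    stopifnot(is.character(extra), !is.null(names(extra)))
    pats <- c(pats, purrr::imap(extra, ~ parse_pattern(.x)))
  }
  pats
}
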