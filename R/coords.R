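#' Parse a genome-interval specifier
#'
#' Parses colon-separated interval specifiers of the form
#' `"assembly:chrom:start:end:strand"` (e.g. `"GRCh38:11:94541840:94543879:1"`),
#' the compact notation used to report promoter and binding-site intervals.
#' Coordinates are 1-based and fully closed, so a specifier with
#' `start == end` denotes a single base.
#'
#' @param spec Character vector of interval specifiers.
#' @return A tibble with columns `assembly`, `chrom`, `start`, `end`,
#'   `strand` (kept as given, typically `"1"`/`"-1"`) and `width` (bp).
#' @examples
#' parse_region_spec("GRCh38:11:94541840:94543879:1")
#' @export
parse_region_spec <- function(spec) {
  stopifnot(is.character(spec), length(spec) >= 1)
  parts <- stringr::str_split(spec, stringr::fixed(":"))
  bad <- vapply(parts, function(p) length(p) != 5, logical(1))
  if (any(bad)) {
    abort(sprintf(
      "Malformed interval spec (need assembly:chrom:start:end:strand): '%s'",
      spec[bad][1]
    ))
  }
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.numeric(m[, 3]))
  end <- suppressWarnings(as.numeric(m[, 4]))
  if (anyNA(start) || anyNA(end)) {
    abort("Non-numeric start/end in interval spec.")
  }
  if (any(start > end)) {
    abort(sprintf(
      "Interval spec with start > end: '%s'", spec[start > end][1]
    ))
  }
  tibble(
    assembly = m[, 1], chrom = m[, 2],
    start = start, end = end, strand = m[, 5],
    width = end - start + 1
  )
}

#' Length of a 1-based closed genome interval
#'
#' `interval_length("GRCh38:11:94541840:94543879:1")` returns 2040: the
#' number of bases in the interval under the 1-based fully-closed
#' convention (`end - start + 1`).
#'
#' @inheritParams parse_region_spec
#' @return Numeric vector of interval widths in bp.
#' @export
interval_length <- function(spec) {
  parse_region_spec(spec)$width
}
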