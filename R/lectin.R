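#' Subtract averaged background from lectin-array spots
#'
#' Within each background scope (per block by default, or per slide),
#' computes the mean and SD of the spot-local background readings and
#' subtracts the mean from every foreground. Corrected values may be
#' negative at this stage; the effectiveness filter handles them later.
#' Grouping respects a `condition` column when present.
#'
#' @param spots Spot tibble with columns `slide`, `block`, `lectin`,
#'   `foreground`, `background` (fluorescence intensity, a.u.) and
#'   optionally `condition`.
#' @param scope `"block"` (default) or `"slide"`: the unit over which
#'   background statistics are pooled.
#' @return The spot tibble with `bg_mean`, `bg_sd` and `corrected`
#'   columns added. A scope with a single background reading gets
#'   `bg_sd = 0` with a warning.
#' @export
subtract_background <- function(spots, scope = c("block", "slide")) {
  scope <- match.arg(scope)
  need <- c("slide", "block", "lectin", "foreground", "background")
  if (!all(need %in% names(spots))) {
    abort(sprintf("spots must have columns: %s", paste(need, collapse = ", ")))
  }
  if (nrow(spots) == 0) abort("spots is empty.")
  if (any(spots$foreground < 0) || any(spots$background < 0)) {
    abort("foreground and background must be >= 0.")
  }
  keys <- c(intersect("condition", names(spots)), "slide",
            if (scope == "block") "block")
  out <- spots |>
    group_by(across(dplyr::all_of(keys))) |>
    mutate(
      bg_mean = mean(.data$background),
      bg_sd = if (n() > 1) sd(.data$background) else NA_real_
    ) |>
    ungroup() |>
    mutate(corrected = .data$foreground - .data$bg_mean)
  if (anyNA(out$bg_sd)) {
    warn("Background SD undefined for a scope with one spot; treated as 0.")
    out$bg_sd[is.na(out$bg_sd)] <- 0
  }
  out
}

#' Flag effective spots
#'
#' A spot is effective when its raw foreground reaches the background
#' validity threshold `mean_bg + k * sd_bg` of its scope (equivalently,
#' corrected foreground >= k * sd_bg). Ineffective spots are excluded
#' from medians downstream. Raising `k` never increases the number of
#' effective spots.
#'
#' @param spots Output of [subtract_background()].
#' @param k Number of background SDs above the mean background required
#'   (default 2).
#' @return The tibble with a logical `effective` column added.
#' @export
flag_effective <- function(spots, k = 2) {
  if (!all(c("bg_mean", "bg_sd", "corrected") %in% names(spots))) {
    abort("Run subtract_background() before flag_effective().")
  }
  mutate(spots,
         effective = .data$foreground >= .data$bg_mean + k * .data$bg_sd)
}

#' Per-block global-median normalization
#'
#' For each block, takes the median of the effective spots of each
#' lectin and divides it by the sum of those medians over all lectins
#' in the block, yielding the normalized fluorescence intensity (NFI).
#' NFIs within a block sum to 1 over the lectins with at least one
#' effective spot, and the profile is invariant to scaling all of a
#' block's foregrounds by a constant. Blocks with no effective spot are
#' dropped with a message.
#'
#' @param spots Output of [flag_effective()].
#' @return Block-profile tibble: (`condition`,) `slide`, `block`,
#'   `lectin`, `median_fi`, `nfi`.
#' @export
normalize_blocks <- function(spots) {
  if (!"effective" %in% names(spots)) {
    abort("Run flag_effective() before normalize_blocks().")
  }
  keys <- c(intersect("condition", names(spots)), "slide", "block")
  eff <- filter(spots, .data$effective)
  all_blocks <- distinct(spots, across(dplyr::all_of(keys)))
  kept_blocks <- distinct(eff, across(dplyr::all_of(keys)))
  dropped <- anti_join(all_blocks, kept_blocks, by = keys)
  if (nrow(dropped) > 0) {
    message(nrow(dropped), " block(s) dropped: no effective spots.")
  }
  eff |>
    group_by(across(dplyr::all_of(c(keys, "lectin")))) |>
    summarise(median_fi = median(.data$corrected), .groups = "drop_last") |>
    mutate(nfi = .data$median_fi / sum(.data$median_fi)) |>
    ungroup()
}

#' Aggregate block-level NFIs per lectin
#'
#' Averages each lectin's normalized value over its replicate blocks
#' (nine at the default three slides x three blocks) and records the SD
#' and the number of contributing blocks.
#'
#' @param profiles Output of [normalize_blocks()].
#' @return Summary tibble: (`condition`,) `lectin`, `mean_nfi`,
#'   `sd_nfi`, `n_blocks`.
#' @export
aggregate_lectins <- function(profiles) {
  need <- c("slide", "block", "lectin", "nfi")
  if (!all(need %in% names(profiles))) {
    abort(sprintf("profiles must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  keys <- c(intersect("condition", names(profiles)), "lectin")
  profiles |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(
      mean_nfi = mean(.data$nfi),
      sd_nfi = if (n() > 1) sd(.data$nfi) else 0,
      n_blocks = n(),
      .groups = "drop"
    )
}

# Paired t-test p-value robust to zero-variance differences: identical
# pairs give p = 1, a constant non-zero shift gives p = 0.
.paired_p <- function(t_vals, c_vals) {
  d <- t_vals - c_vals
  if (length(d) < 2) return(NA_real_)
  if (isTRUE(all.equal(sd(d), 0)) || sd(d) == 0) {
    return(if (isTRUE(all.equal(mean(d), 0))) 1 else 0)
  }
  t.test(t_vals, c_vals, paired = TRUE)$p.value
}

#' Call differential glycans between two conditions
#'
#' Compares per-lectin mean NFIs between a treatment and a control
#' condition. The fold change is `mean NFI(treatment) / mean NFI(control)`
#' and significance comes from a two-sided paired Student's t-test on
#' the block-level NFIs, pairing blocks by (slide, block) across
#' conditions. A lectin is called `UP`/`DOWN` only when both the fold
#' criterion of the tier and `p < alpha` hold. Two tiers are reported:
#' `STRICT` (fold >= 2.0 or <= 0.5) and `REPORTED` (fold > 1.5 or
#' < 0.67). No multiple-testing correction is applied by default;
#' `p_adjust = "BH"` switches the significance test to
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param profiles Block profiles from [normalize_blocks()] carrying a
#'   `condition` column with both conditions.
#' @param control,treatment Values of `condition` to compare.
#' @param alpha Significance level (default 0.05).
#' @param tiers Named list of `c(lower, upper)` fold thresholds;
#'   defaults to the STRICT and REPORTED tiers. STRICT bounds are
#'   inclusive, REPORTED bounds exclusive, matching their definitions.
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust].
#' @return A `lectin_differential` tibble: one row per lectin per tier
#'   with `lectin`, `mean_nfi_control`, `mean_nfi_treatment`,
#'   `fold_change`, `p_value` (and `p_adj` if requested), `tier`,
#'   `call` (`UP`/`DOWN`/`UNCHANGED`). Lectins with a zero control mean
#'   get `call = "DEFERRED"` (fold undefined).
#' @export
differential_glycans <- function(profiles, control = "control",
                                 treatment = "treatment", alpha = 0.05,
                                 tiers = list(STRICT = c(0.5, 2.0),
                                              REPORTED = c(0.67, 1.5)),
                                 p_adjust = "none") {
  need <- c("condition", "slide", "block", "lectin", "nfi")
  if (!all(need %in% names(profiles))) {
    abort(sprintf("profiles must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  if (!all(c(control, treatment) %in% profiles$condition)) {
    abort("Both conditions must be present in profiles.")
  }
  paired <- profiles |>
    filter(.data$condition %in% c(control, treatment)) |>
    mutate(condition = if_else(.data$condition == control, "c", "t")) |>
    select("condition", "slide", "block", "lectin", "nfi") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "nfi") |>
    filter(!is.na(.data$c), !is.na(.data$t))
  stats_tbl <- paired |>
    group_by(.data$lectin) |>
    summarise(
      mean_nfi_control = mean(.data$c),
      mean_nfi_treatment = mean(.data$t),
      n_pairs = n(),
      p_value = .paired_p(.data$t, .data$c),
      .groups = "drop"
    ) |>
    mutate(fold_change = if_else(.data$mean_nfi_control > 0,
                                 .data$mean_nfi_treatment /
                                   .data$mean_nfi_control,
                                 NA_real_))
  if (!identical(p_adjust, "none")) {
    stats_tbl <- mutate(stats_tbl,
                        p_adj = p.adjust(.data$p_value, method = p_adjust))
  }
  p_sig <- if (identical(p_adjust, "none")) stats_tbl$p_value
           else stats_tbl$p_adj
  out <- purrr::imap_dfr(tiers, function(th, tier_name) {
    inclusive <- identical(tier_name, "STRICT")
    up <- if (inclusive) stats_tbl$fold_change >= th[2]
          else stats_tbl$fold_change > th[2]
    down <- if (inclusive) stats_tbl$fold_change <= th[1]
            else stats_tbl$fold_change < th[1]
    call <- dplyr::case_when(
      is.na(stats_tbl$fold_change) ~ "DEFERRED",
      up & p_sig < alpha ~ "UP",
      down & p_sig < alpha ~ "DOWN",
      TRUE ~ "UNCHANGED"
    )
    mutate(stats_tbl, tier = tier_name, call = call)
  })
  structure(
    arrange(out, .data$tier, .data$lectin),
    class = c("lectin_differential", class(out)),
    alpha = alpha, tiers = tiers, p_adjust = p_adjust
  )
}

#' Run the full lectin-array protocol
#'
#' Chains background subtraction, effectiveness filtering, per-block
#' global-median normalization, per-lectin aggregation and differential
#' calling in one call.
#'
#' @inheritParams subtract_background
#' @inheritParams flag_effective
#' @inheritParams differential_glycans
#' @return List with `spots` (corrected/flagged), `profiles`,
#'   `summaries` and `differential`.
#' @export
lectin_analyze <- function(spots, scope = "block", k = 2,
                           control = "control", treatment = "treatment",
                           alpha = 0.05, p_adjust = "none") {
  flagged <- spots |>
    subtract_background(scope = scope) |>
    flag_effective(k = k)
  profiles <- normalize_blocks(flagged)
  list(
    spots = flagged,
    profiles = profiles,
    summaries = aggregate_lectins(profiles),
    differential = differential_glycans(profiles, control = control,
                                        treatment = treatment,
                                        alpha = alpha, p_adjust = p_adjust)
  )
}

#' @export
print.lectin_differential <- function(x, ...) {
  calls <- filter(as_tibble(x), .data$call %in% c("UP", "DOWN"))
  cat("<lectin_differential> ", length(unique(x$lectin)), " lectins; ",
      nrow(calls), " UP/DOWN calls across ",
      length(attr(x, "tiers")), " tiers (alpha ", attr(x, "alpha"), ")\n",
      sep = "")
  NextMethod()
}

#' @describeIn differential_glycans Return the calls as a plain tibble.
#' @param x A `lectin_differential`.
#' @param ... Unused.
#' @method tidy lectin_differential
#' @export
tidy.lectin_differential <- function(x, ...) {
  as_tibble(unclass2_tbl(x))
}

unclass2_tbl <- function(x) {
  class(x) <- setdiff(class(x), "lectin_differential")
  x
}

#' @describeIn differential_glycans One row per tier with call counts.
#' @method glance lectin_differential
#' @export
glance.lectin_differential <- function(x, ...) {
  as_tibble(unclass2_tbl(x)) |>
    group_by(.data$tier) |>
    summarise(
      n_lectins = n(),
      n_up = sum(.data$call == "UP"),
      n_down = sum(.data$call == "DOWN"),
      .groups = "drop"
    ) |>
    mutate(alpha = attr(x, "alpha"))
}

#' The synthetic 37-lectin panel shipped with the package
#'
#' A representative 37-lectin microarray panel (standard lectin names
#' with abbreviated glycan-binding annotations) used as the default
#' lectin universe by the simulators. It is a synthetic stand-in for a
#' real array layout, not measured data.
#'
#' @return Tibble with columns `lectin` and `specificity`.
#' @export
lectin_panel <- function() {
  path <- system.file("extdata", "lectin_panel_synthetic.tsv",
                      package = "chipglyco", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, comment = "#")
}
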