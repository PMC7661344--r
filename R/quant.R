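#' Relative expression by the 2^-ddCt method
#'
#' Computes relative expression of a target gene between two conditions,
#' normalized to a reference gene, from raw qPCR cycle thresholds.
#' Replicates are averaged on the Ct scale before differencing:
#' dCt = mean Ct(target) - mean Ct(reference) within each condition,
#' ddCt = dCt(treatment) - dCt(control), and the returned ratio is
#' 2^(-ddCt).
#'
#' @param ct_target_treatment,ct_reference_treatment,ct_target_control,ct_reference_control
#'   Numeric vectors of replicate Ct values (cycles, all > 0).
#' @return A single relative-expression fold (treatment vs control).
#' @examples
#' ddct(25, 20, 24, 20) # ddCt = 1 -> 0.5
#' @export
ddct <- function(ct_target_treatment, ct_reference_treatment,
                 ct_target_control, ct_reference_control) {
  for (x in list(ct_target_treatment, ct_reference_treatment,
                 ct_target_control, ct_reference_control)) {
    if (length(x) < 1 || anyNA(x) || any(x <= 0)) {
      abort("All Ct vectors must be non-empty, positive and NA-free.")
    }
  }
  dct_t <- mean(ct_target_treatment) - mean(ct_reference_treatment)
  dct_c <- mean(ct_target_control) - mean(ct_reference_control)
  2^(-(dct_t - dct_c))
}

#' Tidy 2^-ddCt over a Ct table
#'
#' Applies [ddct()] to every target gene in a long Ct table. The table
#' needs one reference-gene record per condition; target replicates and
#' reference replicates are averaged per condition before differencing.
#'
#' @param ct_tbl Tibble with columns `condition`, `gene_id`, `role`
#'   (`"target"`/`"reference"`) and `ct` (one row per replicate).
#' @param control,treatment Values of `condition` to compare.
#' @return Tibble with one row per target gene: `gene_id`, `ddct`,
#'   `ratio` (2^-ddCt) and per-condition replicate counts.
#' @export
ddct_ratio <- function(ct_tbl, control = "control", treatment = "treatment") {
  need <- c("condition", "gene_id", "role", "ct")
  if (!all(need %in% names(ct_tbl))) {
    abort(sprintf("ct_tbl must have columns: %s", paste(need, collapse = ", ")))
  }
  ref <- ct_tbl |> filter(.data$role == "reference")
  if (!all(c(control, treatment) %in% ref$condition)) {
    abort("Missing reference-gene records for one of the conditions.")
  }
  ref_mean <- ref |>
    group_by(.data$condition) |>
    summarise(ref_ct = mean(.data$ct), .groups = "drop")
  tgt <- ct_tbl |>
    filter(.data$role == "target",
           .data$condition %in% c(control, treatment)) |>
    group_by(.data$gene_id, .data$condition) |>
    summarise(ct = mean(.data$ct), n_reps = n(), .groups = "drop") |>
    left_join(ref_mean, by = "condition") |>
    mutate(dct = .data$ct - .data$ref_ct)
  wide <- tgt |>
    select("gene_id", "condition", "dct", "n_reps") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("dct", "n_reps"))
  dct_t <- wide[[paste0("dct_", treatment)]]
  dct_c <- wide[[paste0("dct_", control)]]
  tibble(
    gene_id = wide$gene_id,
    ddct = dct_t - dct_c,
    ratio = 2^(-(dct_t - dct_c)),
    n_reps_control = wide[[paste0("n_reps_", control)]],
    n_reps_treatment = wide[[paste0("n_reps_", treatment)]]
  )
}

#' ChIP-qPCR fold enrichment over IgG
#'
#' Enrichment of the specific-antibody (IP) signal over the non-specific
#' IgG control at one amplicon, from mean Ct values:
#' `fold = 2^(meanCt(IgG) - meanCt(IP))`. When an input-chromatin Ct is
#' supplied, each arm is first expressed as percent input
#' (`2^(Ct_input - Ct_arm)`, with `input_dilution_log2` subtracted from
#' the raw input Ct to account for the input dilution factor) and the
#' ratio of percent-inputs is returned; with a shared input this is
#' algebraically identical to the no-input form.
#'
#' @param ct_ip,ct_igg Numeric vectors of replicate Ct values.
#' @param ct_input Optional numeric vector of input-chromatin Ct values.
#' @param input_dilution_log2 log2 of the input dilution factor (e.g.
#'   3.32 for a 10 % input); default 0.
#' @return A single fold-enrichment value.
#' @examples
#' chip_fold_over_igg(ct_ip = 28, ct_igg = 30) # 2^2 = 4
#' @export
chip_fold_over_igg <- function(ct_ip, ct_igg, ct_input = NULL,
                               input_dilution_log2 = 0) {
  stopifnot(length(ct_ip) >= 1, length(ct_igg) >= 1,
            all(ct_ip > 0), all(ct_igg > 0))
  if (is.null(ct_input)) {
    return(2^(mean(ct_igg) - mean(ct_ip)))
  }
  stopifnot(all(ct_input > 0))
  ct_in <- mean(ct_input) - input_dilution_log2
  pct_ip <- 2^(ct_in - mean(ct_ip))
  pct_igg <- 2^(ct_in - mean(ct_igg))
  pct_ip / pct_igg
}

#' Tidy ChIP-qPCR enrichment over a Ct table
#'
#' @param chip_tbl Tibble with columns `fragment_id`, `antibody`
#'   (values including `ip` and `igg`, optionally `input`) and `ct`
#'   (one row per replicate).
#' @param ip,igg,input Values of `antibody` naming the specific
#'   antibody, the IgG control and (optionally) the input chromatin.
#' @inheritParams chip_fold_over_igg
#' @return Tibble with one row per fragment: `fragment_id`, `fold`.
#' @export
chip_qpcr_fold <- function(chip_tbl, ip = "MyoD1", igg = "IgG",
                           input = "input", input_dilution_log2 = 0) {
  need <- c("fragment_id", "antibody", "ct")
  if (!all(need %in% names(chip_tbl))) {
    abort(sprintf("chip_tbl must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  chip_tbl |>
    group_by(.data$fragment_id) |>
    summarise(
      fold = {
        cts <- split(.data$ct, .data$antibody)
        if (is.null(cts[[ip]]) || is.null(cts[[igg]])) {
          abort(sprintf("Fragment '%s' lacks %s or %s records.",
                        .data$fragment_id[1], ip, igg))
        }
        chip_fold_over_igg(cts[[ip]], cts[[igg]], cts[[input]],
                           input_dilution_log2)
      },
      .groups = "drop"
    )
}

#' Dual-luciferase relative activity
#'
#' Firefly luciferase activity is scaled to activity per 1000 cells,
#' normalized by the matched Renilla activity (also per 1000 cells), and
#' expressed relative to a designated control construct, whose relative
#' activity is 1 by definition. Replicate wells of a construct are
#' averaged on the normalized scale.
#'
#' @param luc_tbl Tibble with columns `construct_id`, `firefly`,
#'   `renilla` (relative light units, renilla > 0) and optionally
#'   `cell_count` (> 0; default 1000 per well).
#' @param control_id Construct used as the reference.
#' @return Tibble with one row per construct: `construct_id`,
#'   `normalized` (firefly/renilla per 1000 cells) and `relative`.
#' @export
luciferase_relative <- function(luc_tbl, control_id) {
  need <- c("construct_id", "firefly", "renilla")
  if (!all(need %in% names(luc_tbl))) {
    abort(sprintf("luc_tbl must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  if (!"cell_count" %in% names(luc_tbl)) {
    luc_tbl <- mutate(luc_tbl, cell_count = 1000)
  }
  if (any(luc_tbl$renilla <= 0)) abort("Renilla readings must be > 0.")
  if (any(luc_tbl$cell_count <= 0)) abort("Cell counts must be > 0.")
  if (!control_id %in% luc_tbl$construct_id) {
    abort(sprintf("Control construct '%s' not present.", control_id))
  }
  out <- luc_tbl |>
    mutate(
      normalized = (.data$firefly / (.data$cell_count / 1000)) /
        (.data$renilla / (.data$cell_count / 1000))
    ) |>
    group_by(.data$construct_id) |>
    summarise(normalized = mean(.data$normalized), .groups = "drop")
  ctrl <- out$normalized[out$construct_id == control_id]
  mutate(out, relative = .data$normalized / ctrl)
}
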