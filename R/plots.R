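#' Plot the region-class distribution of classified peaks
#'
#' Bar chart of the fraction of peaks in each of the five region
#' classes, in priority order.
#'
#' @param classified Output of [classify_peaks()] (or a
#'   [region_distribution()] tibble).
#' @return A ggplot object.
#' @export
plot_region_distribution <- function(classified) {
  dist <- if ("fraction" %in% names(classified)) classified
          else region_distribution(classified)
  dist$region <- factor(dist$region, levels = region_classes())
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$region, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "Fraction of peaks") +
    ggplot2::theme_minimal()
}

#' @describeIn filter_and_intersect Per-chromosome counts of filtered
#'   and common peaks as a grouped bar chart.
#' @param object A `peak_comparison`.
#' @method autoplot peak_comparison
#' @export
autoplot.peak_comparison <- function(object, ...) {
  long <- object$per_chrom |>
    tidyr::pivot_longer(c("m1", "m2", "common"),
                        names_to = "set", values_to = "n") |>
    mutate(chrom = factor(.data$chrom, levels = object$per_chrom$chrom),
           set = factor(.data$set, levels = c("m1", "m2", "common"),
                        labels = c("M1 (vs IgG)", "M2 (vs input)",
                                   "common")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$chrom, y = .data$n,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Peaks passing filter", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn differential_glycans log2 fold-change bar chart per
#'   lectin, coloured by call and faceted by tier.
#' @param object A `lectin_differential`.
#' @method autoplot lectin_differential
#' @export
autoplot.lectin_differential <- function(object, ...) {
  tbl <- tidy(object) |>
    filter(!is.na(.data$fold_change)) |>
    mutate(log2fc = log2(.data$fold_change))
  ggplot2::ggplot(tbl, ggplot2::aes(
    x = stats::reorder(.data$lectin, .data$log2fc),
    y = .data$log2fc, fill = .data$call
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~tier) +
    ggplot2::scale_fill_manual(values = c(
      UP = "#c0392b", DOWN = "#2980b9", UNCHANGED = "grey70",
      DEFERRED = "grey40"
    )) +
    ggplot2::labs(x = NULL, y = "log2 fold change (treatment / control)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
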