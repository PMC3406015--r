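# ggplot2 displays for the main result types.

#' Plot the permutation null against the observed overlap
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$overlap_bp)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(
      x = "overlap (bp) under random placement",
      y = "permutations",
      title = sprintf("Observed %s bp, fold %.2f, p = %.3g",
                      format(object$observed, big.mark = ","),
                      object$fold, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Cumulative distributions of normalized substitution rates
#'
#' Mirrors the usual constraint display: one ECDF of `d / d_AR` per
#' group, with the neutral expectation at 1 dashed.
#'
#' @param object A `constraint_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.constraint_summary <- function(object, ...) {
  ggplot2::ggplot(object$ratios,
                  ggplot2::aes(x = .data$ratio, colour = .data$group)) +
    ggplot2::stat_ecdf(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "goldenrod") +
    ggplot2::labs(x = expression(d / d[AR]),
                  y = "cumulative proportion of regions",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Conservation-category composition per locus group
#'
#' @param calls Tibble with `category` and a `group` column.
#' @return A ggplot (stacked proportions).
#' @export
plot_turnover <- function(calls) {
  calls <- as_tibble(calls)
  stopifnot(all(c("group", "category") %in% names(calls)))
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$group,
                                      fill = .data$category)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::labs(x = NULL, y = "fraction of loci", fill = "category") +
    ggplot2::theme_minimal()
}

#' Fold-difference distributions by gene group
#'
#' Boxplots of ln fold-differences per group with the housekeeping
#' baseline median as a dashed line.
#'
#' @param folds Tibble with `group`, `value`.
#' @param baseline_median Housekeeping baseline median (default 0).
#' @return A ggplot.
#' @export
plot_fold_differences <- function(folds, baseline_median = 0) {
  folds <- as_tibble(folds)
  ggplot2::ggplot(folds, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, fill = "grey85") +
    ggplot2::geom_hline(yintercept = baseline_median, linetype = "dashed",
                        colour = "goldenrod") +
    ggplot2::labs(x = NULL, y = "ln fold-difference (X / Y)") +
    ggplot2::theme_minimal()
}
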