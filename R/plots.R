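#' Plot per-sequence concordance ratios
#'
#' @param object a `match_stats` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.match_stats <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$seq_id, y = .data$ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(min(object$ratio) * 0.99, 1)) +
    ggplot2::labs(x = NULL, y = "Match / (Match + Mismatch)",
                  title = "Base-level concordance in synteny blocks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot repeat-ratio distributions by window group
#'
#' Boxplots of windowed repeat ratios in closed-gap windows versus the
#' rest, annotated with the Mann-Whitney p-value.
#'
#' @param x an `mwu_test` returned by [compare_window_groups()].
#' @return a ggplot.
#' @export
plot_window_groups <- function(x) {
  w <- attr(x, "windows")
  if (is.null(w)) abort("x must come from compare_window_groups()")
  ggplot2::ggplot(w, ggplot2::aes(x = .data$group, y = .data$ratio,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Repeat ratio per window",
                  subtitle = sprintf("Mann-Whitney U = %g, p = %.3g",
                                     x$U, x$p_value)) +
    ggplot2::theme_minimal()
}

#' Histogram of connected-contig lengths (log-scaled bins)
#'
#' @param lengths tibble from [connected_contig_lengths()].
#' @param bins number of log-uniform bins.
#' @return a ggplot.
#' @export
plot_contig_lengths <- function(lengths, bins = 30) {
  ggplot2::ggplot(lengths, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Connected contig length (bp)", y = "Contigs") +
    ggplot2::theme_minimal()
}

#' Histogram of per-gap physical coverage
#'
#' Well-supported joins cluster around the library depth; unsupported
#' (false) joins pile up near zero, giving the characteristic bimodal
#' shape.
#'
#' @param gaps tibble from [physical_coverage_at_gaps()].
#' @param bins histogram bins.
#' @return a ggplot.
#' @export
plot_gap_coverage <- function(gaps, bins = 40) {
  ggplot2::ggplot(gaps, ggplot2::aes(x = .data$coverage)) +
    ggplot2::geom_histogram(bins = bins, fill = "darkorange") +
    ggplot2::labs(x = "Physical coverage over gap", y = "Gaps") +
    ggplot2::theme_minimal()
}

#' Per-sequence QV barplot
#'
#' @param qv tibble from [qv_per_sequence()].
#' @return a ggplot.
#' @export
plot_qv <- function(qv) {
  ggplot2::ggplot(qv, ggplot2::aes(x = .data$seq_id, y = .data$qv)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::labs(x = NULL, y = "QV") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
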