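# ggplot2 views of the two result types people actually plot: the per-pair
# Ks vs Ka/Ks scatter and the sliding-window selection scan.

#' Scatter plot of Ka/Ks against Ks for duplicated pairs
#'
#' X axis: synonymous distance Ks; Y axis: Ka/Ks, with the neutral line at 1.
#'
#' @param pairs tibble from [kaks_report()]`$pairs` (columns Ks, ka_ks).
#' @return A ggplot object.
#' @export
plot_kaks_scatter <- function(pairs) {
  df <- pairs[!is.na(pairs$ka_ks) & !is.na(pairs$Ks), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$Ks, y = .data$ka_ks)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Ks", y = "Ka/Ks") +
    ggplot2::theme_minimal()
}

#' Sliding-window Ka/Ks profile for one or more pairs
#'
#' @param windows tibble from [kaks_report()]`$windows` or
#'   [sliding_window_kaks()]; a `gene_a`/`gene_b` pair label is used for
#'   facetting when present.
#' @return A ggplot object (windows with undefined ratios are gaps, never
#'   fabricated values).
#' @export
plot_kaks_windows <- function(windows) {
  df <- windows
  if (all(c("gene_a", "gene_b") %in% names(df))) {
    df$pair <- paste(df$gene_a, df$gene_b, sep = " / ")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$win_start, y = .data$ka_ks)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "alignment position (bp)", y = "Ka/Ks") +
    ggplot2::theme_minimal()
  if ("pair" %in% names(df)) p <- p + ggplot2::facet_wrap(~pair)
  p
}

#' Per-site posterior profile of a divergence fit
#'
#' @param x a `divergence_fit`.
#' @param ... unused.
#' @return A ggplot object: site posteriors with the critical-site cutoff.
#' @method autoplot divergence_fit
#' @export
autoplot.divergence_fit <- function(x, ...) {
  ggplot2::ggplot(x$qk, ggplot2::aes(x = .data$site, y = .data$qk)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = x$qk_threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "alignment site", y = expression(Q[k]),
                  title = sprintf("Type %s divergence, theta = %.3f", x$type, x$theta)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
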