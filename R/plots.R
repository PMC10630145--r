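# ggplot2 visualisations for the main result types.

#' @export
autoplot.sfs <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "derived allele count", y = "sites",
                  title = object$class_label) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sfs_pair <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(x = "derived allele count", y = "sites") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dfe_avg <- function(object, ...) {
  df <- object$avg_discretized
  df$bin <- factor(sprintf("(%g, %g]", df$lower, df$upper),
                   levels = sprintf("(%g, %g]", df$lower, df$upper))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$mass)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "scaled fitness effect (Ne s)",
                  y = "fraction of new mutations",
                  title = "model-averaged discretized DFE") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Plot focal-vs-reference load statistics
#'
#' Point estimates with jackknife confidence bars, one panel per statistic,
#' from the tibble produced by [load_statistics()].
#'
#' @param stats_tbl Output of [load_statistics()] (optionally row-bound over
#'   several focal populations with an added `focal` column).
#' @return A ggplot object.
#' @export
plot_load_statistics <- function(stats_tbl) {
  df <- stats_tbl
  if (!"focal" %in% names(df)) df$focal <- "focal"
  df$lab <- paste0(df$statistic, " (", df$class, ")")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$focal, y = .data$estimate)) +
    ggplot2::geom_point(shape = 18, size = 3) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.2) +
    ggplot2::facet_wrap(~lab, scales = "free_y") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = NULL, y = "estimate") +
    ggplot2::theme_minimal()
}
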