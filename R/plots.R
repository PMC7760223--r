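# ggplot2 views of the main result types.

#' Forest-style plot of a consensus fit
#'
#' Per-plate posterior means with 95% credible intervals and the consensus
#' value per condition, with a reference line at 100% viability.
#'
#' @param object An `ali_consensus` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ali_consensus <- function(object, ...) {
  td <- tidy(object)
  td$kind <- ifelse(td$term == "consensus", "consensus", "plate")
  ggplot2::ggplot(td[td$term != "tau", ],
                  ggplot2::aes(x = .data$estimate, y = .data$term,
                               colour = .data$kind)) +
    ggplot2::geom_vline(xintercept = 100, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition), scales = "free_y") +
    ggplot2::labs(x = "viability (% of incubator control)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Control chart plot
#'
#' @param chart A tibble from [control_chart_series()].
#' @return A ggplot object.
#' @export
plot_control_chart <- function(chart) {
  ggplot2::ggplot(chart, ggplot2::aes(x = .data$date,
                                      y = .data$mean_absorbance)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$center),
                        colour = "grey40") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$lower_limit),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$upper_limit),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outside_limits)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = NULL, y = "mean absorbance (AU)",
                  title = unique(chart$condition)) +
    ggplot2::theme_minimal()
}

#' Size-distribution plot
#'
#' Number concentration against diameter (log x-axis), one line per scan,
#' with detected modes of the mean distribution marked.
#'
#' @param scans Tibble with `scan_id`, `diameter_nm`, `number_per_cm3`.
#' @param window Smoothing window for the mode markers (see
#'   [detect_modes()]).
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(scans, window = 3L) {
  mean_dist <- scans |>
    dplyr::group_by(.data$diameter_nm) |>
    dplyr::summarise(number_per_cm3 = mean(.data$number_per_cm3),
                     .groups = "drop")
  modes <- detect_modes(mean_dist, window = window)
  p <- ggplot2::ggplot(scans, ggplot2::aes(x = .data$diameter_nm,
                                           y = .data$number_per_cm3,
                                           group = .data$scan_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_line(data = mean_dist, ggplot2::aes(group = NULL),
                       linewidth = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mobility diameter (nm)",
                  y = expression(dN ~ (cm^-3))) +
    ggplot2::theme_minimal()
  if (length(modes))
    p <- p + ggplot2::geom_vline(xintercept = modes, linetype = "dotted")
  p
}

#' PCA score plot of binned spectra
#'
#' @param object An `ali_pca` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ali_pca <- function(object, ...) {
  ev <- object$explained_variance
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ev[2]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
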