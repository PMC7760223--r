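# Shewhart-style control charting and dispersion statistics for the
# in-process control measurements (incubator negative control, medium blank,
# positive control).

control_insert_means <- function(readings, condition) {
  inserts <- aggregate_technical_replicates(readings)
  df <- inserts[inserts$condition == condition, ]
  if (!nrow(df))
    abort(sprintf("No wells for condition '%s'.", condition),
          class = "alidose_input_error")
  if (!"date" %in% names(df))
    abort("Control charting needs a `date` column.",
          class = "alidose_input_error")
  df
}

#' Control-chart series for an in-process control
#'
#' Per-date mean absorbance of a control condition with a Shewhart-style
#' individuals chart on the per-date means: centre line at the grand mean,
#' limits at +/- 3 standard deviations of the per-date means, and a flag for
#' days outside the limits.
#'
#' @param readings Per-replicate plate table (see
#'   [aggregate_technical_replicates()]); needs `date`.
#' @param condition Control condition to chart (default
#'   `"incubator_control"`).
#' @return Tibble with one row per date: `date`, `condition`,
#'   `mean_absorbance`, `n_wells`, `center`, `lower_limit`, `upper_limit`,
#'   `outside_limits`.
#' @export
#' @examples
#' r <- simulate_plate_readings(ali_sim_config(seed = 3, n_plates = 5))
#' control_chart_series(r, "medium_blank")
control_chart_series <- function(readings, condition = "incubator_control") {
  df <- control_insert_means(readings, condition)
  daily <- df |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(mean_absorbance = mean(.data$abs450_mean),
                     n_wells = dplyr::n(), .groups = "drop")
  if (nrow(daily) < 2L)
    abort("At least 2 dates are required for a control chart.",
          class = "alidose_input_error")
  center <- mean(daily$mean_absorbance)
  s <- sd(daily$mean_absorbance)
  daily |>
    dplyr::mutate(condition = condition, center = center,
                  lower_limit = center - 3 * s, upper_limit = center + 3 * s,
                  outside_limits = .data$mean_absorbance < center - 3 * s |
                    .data$mean_absorbance > center + 3 * s) |>
    dplyr::select("date", "condition", "mean_absorbance", "n_wells",
                  "center", "lower_limit", "upper_limit", "outside_limits")
}

#' Coefficient-of-variation series for an in-process control
#'
#' Per-date COV (100 x sample sd / mean) of a control's insert-level
#' absorbances. COV is scale-invariant, so it isolates pipetting and handling
#' variability from signal level. Days whose mean absorbance is zero get a
#' missing COV.
#'
#' @inheritParams control_chart_series
#' @return Tibble with one row per date: `date`, `condition`, `cov_pct`,
#'   `n_wells`.
#' @export
cov_series <- function(readings, condition = "incubator_control") {
  df <- control_insert_means(readings, condition)
  out <- df |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(cov_pct = if (dplyr::n() < 2L) NA_real_ else if
                     (mean(.data$abs450_mean) == 0) NA_real_ else
                       100 * sd(.data$abs450_mean) / mean(.data$abs450_mean),
                     n_wells = dplyr::n(), .groups = "drop")
  if (any(out$n_wells < 2L))
    warn("Some dates have fewer than 2 wells; their COV is missing.")
  dplyr::mutate(out, condition = condition,
                .after = "date")
}

#' Dynamic-range check for the positive control
#'
#' The assay's full dynamic range is demonstrated when the positive control
#' (complete loss of viability) is statistically indistinguishable from the
#' medium blank, i.e. the 95% credible interval of the difference of their
#' consensus viabilities contains zero. Uses the hierarchical consensus
#' machinery's pairwise-equality call.
#'
#' @param viability Viability records (see [compute_viability()]) containing
#'   both conditions.
#' @param positive,blank Condition labels.
#' @param spec A [consensus_model_spec()].
#' @return One-row tibble: `pass`, `positive_mean`, `blank_mean`,
#'   `diff_low`, `diff_high`.
#' @export
dynamic_range_check <- function(viability, positive = "positive_control",
                                blank = "medium_blank",
                                spec = consensus_model_spec()) {
  for (lbl in c(positive, blank)) {
    if (!lbl %in% viability$condition)
      abort(sprintf("Condition '%s' missing from the viability records.", lbl),
            class = "alidose_input_error")
  }
  fit <- fit_consensus(viability, spec, conditions = c(positive, blank))
  sig <- significance_calls(fit)
  pw <- sig$pairwise[1, ]
  est <- tidy(fit, parameters = "consensus")
  tibble::tibble(pass = pw$equal,
                 positive_mean = est$estimate[est$condition == positive],
                 blank_mean = est$estimate[est$condition == blank],
                 diff_low = pw$diff_low, diff_high = pw$diff_high)
}

#' Blank signal as a fraction of the control signal
#'
#' `100 * blank mean / control mean`: how much of the control absorbance is
#' assay background rather than formazan produced by cells (~3% in a
#' well-behaved run).
#'
#' @param blank_mean,control_mean Mean absorbances (control > 0).
#' @return Percentage (vectorised).
#' @export
blank_fraction <- function(blank_mean, control_mean) {
  if (any(control_mean <= 0))
    abort("`control_mean` must be > 0.", class = "alidose_input_error")
  100 * blank_mean / control_mean
}
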