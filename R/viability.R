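# WST-1 viability normalisation: raw plate-reader tables -> per-insert
# percentage viability relative to the incubator negative control.

#' Average technical replicates per insert
#'
#' The assay pipettes three technical replicates of each insert's supernatant
#' into a 96-well plate; they estimate one underlying insert absorbance and
#' are averaged (arithmetic mean, both wavelengths) before the viability
#' equation is applied.
#'
#' @param readings Tibble of per-replicate rows with columns `plate_id`,
#'   `date`, `condition`, `insert_id`, `replicate`, `abs450`, `abs562`.
#' @return One row per insert: `plate_id`, `date`, `condition`, `insert_id`,
#'   `abs450_mean`, `abs562_mean`, `n_replicates`.
#' @export
aggregate_technical_replicates <- function(readings) {
  required <- c("plate_id", "condition", "insert_id", "abs450", "abs562")
  missing_cols <- setdiff(required, names(readings))
  if (length(missing_cols))
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "alidose_input_error")
  bad <- readings[!is.finite(readings$abs450) | !is.finite(readings$abs562), ]
  if (nrow(bad))
    abort(paste0("Non-finite absorbance for insert(s): ",
                 paste(unique(bad$insert_id), collapse = ", ")),
          class = "alidose_input_error")
  if (any(readings$abs450 < 0) || any(readings$abs562 < 0))
    abort("Absorbances must be non-negative.", class = "alidose_input_error")
  grp <- intersect(c("plate_id", "date", "condition", "insert_id"),
                   names(readings))
  readings |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(abs450_mean = mean(.data$abs450),
                     abs562_mean = mean(.data$abs562),
                     n_replicates = dplyr::n(), .groups = "drop")
}

#' Percentage viability relative to the incubator control
#'
#' `100 * (test - blank) / (negative_control - blank)`: the blank-corrected
#' test absorbance as a percentage of the blank-corrected incubator negative
#' control. The denominator must be positive for the assay to be valid.
#' Values below 0% (test below blank) are returned as computed, not clipped;
#' downstream consensus modelling assumes unclipped Gaussian observations.
#'
#' @param test_mean,blank_mean,negative_control_mean Mean absorbances (AU).
#' @return Numeric percentage viability (vectorised).
#' @export
#' @examples
#' percent_viability(0.275, 0.05, 0.50) # 50
percent_viability <- function(test_mean, blank_mean, negative_control_mean) {
  denom <- negative_control_mean - blank_mean
  if (any(denom <= 0))
    abort("Assay invalid: negative control does not exceed the medium blank.",
          class = "alidose_assay_error")
  100 * (test_mean - blank_mean) / denom
}

#' Flag optical interference at 562 nm
#'
#' The 562 nm wavelength lies outside the formazan absorption spectrum; a
#' signal well above the blank level there indicates bubbles or debris rather
#' than assay chemistry. An insert is flagged when its 562 nm mean exceeds
#' `factor` times the plate-blank 562 nm level.
#'
#' @param abs562_insert Insert mean absorbance at 562 nm.
#' @param abs562_blank Plate blank-level 562 nm absorbance.
#' @param factor Multiplicative threshold (> 0, default 2).
#' @return Logical (vectorised).
#' @export
flag_interference <- function(abs562_insert, abs562_blank, factor = 2) {
  if (any(factor <= 0))
    abort("`factor` must be > 0.", class = "alidose_input_error")
  abs562_insert > factor * abs562_blank
}

#' Compute per-insert viability records from a plate table
#'
#' End-to-end normalisation: technical replicates are averaged per insert,
#' each plate's medium-blank and incubator-control levels are computed from
#' that plate only (cross-plate blanks are never mixed), and every insert gets
#' a percentage viability plus interference and negative-value flags. Blank
#' inserts are retained (their viability scatters around 0%), which downstream
#' QC uses as the assay's floor.
#'
#' @param readings Per-replicate plate table, see
#'   [aggregate_technical_replicates()].
#' @param negative_control,blank Condition labels of the incubator negative
#'   control and the medium blank.
#' @param interference_factor Passed to [flag_interference()].
#' @return Tibble of viability records: `plate_id`, `date`, `condition`,
#'   `insert_id`, `viability_pct`, `interference_flag`, `negative_flag`.
#' @export
#' @examples
#' cfg <- ali_sim_config(seed = 1)
#' compute_viability(simulate_plate_readings(cfg))
compute_viability <- function(readings,
                              negative_control = "incubator_control",
                              blank = "medium_blank",
                              interference_factor = 2) {
  inserts <- aggregate_technical_replicates(readings)
  for (lbl in c(negative_control, blank)) {
    if (!lbl %in% inserts$condition)
      abort(sprintf("Condition '%s' not present in the plate table.", lbl),
            class = "alidose_input_error")
  }
  inserts |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::group_modify(function(df, key) {
      blank450 <- mean(df$abs450_mean[df$condition == blank])
      blank562 <- mean(df$abs562_mean[df$condition == blank])
      neg450 <- mean(df$abs450_mean[df$condition == negative_control])
      if (!length(blank450) || is.nan(blank450) || is.nan(neg450))
        abort(sprintf("Plate '%s' lacks blank or control wells.", key$plate_id),
              class = "alidose_input_error")
      df$viability_pct <- percent_viability(df$abs450_mean, blank450, neg450)
      df$interference_flag <- flag_interference(df$abs562_mean, blank562,
                                                interference_factor)
      df$negative_flag <- df$viability_pct < 0
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::any_of(c("plate_id", "date", "condition", "insert_id",
                                  "viability_pct", "interference_flag",
                                  "negative_flag")))
}
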