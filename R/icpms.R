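# ICP-MS bookkeeping: blank correction, detection limits, recovery screening
# and compartment dose arithmetic for elemental Ce measurements.

#' Detection limits from blank measurements
#'
#' LOD and LOQ are 3 and 10 times the sample standard deviation (n - 1
#' denominator) of the blank measurements, so LOQ/LOD = 10/3 exactly.
#'
#' @param blanks Numeric vector of blank values (>= 2), any consistent unit.
#' @return One-row tibble: `lod`, `loq`, `n_blanks`, `blank_mean`, `blank_sd`.
#' @export
#' @examples
#' lod_loq(c(0.2, 0.5, 0.8)) # lod = 0.9, loq = 3.0
lod_loq <- function(blanks) {
  if (length(blanks) < 2L)
    abort("At least 2 blank measurements are required.",
          class = "alidose_input_error")
  s <- sd(blanks)
  tibble::tibble(lod = 3 * s, loq = 10 * s, n_blanks = length(blanks),
                 blank_mean = mean(blanks), blank_sd = s)
}

#' Blank-correct sample measurements
#'
#' Subtracts the mean of the blank measurements from every sample value.
#' Corrected values below the LOD (3 x blank sd) are flagged, and negative
#' corrected values are retained but flagged — never censored or substituted,
#' so downstream compartment sums stay unbiased.
#'
#' @param data Tibble of sample rows. If `blanks` is `NULL`, rows with
#'   `compartment == "blank"` are used as blanks and removed from the output.
#' @param blanks Optional numeric vector of blank values.
#' @param value_col Name of the measurement column (default `"ce_ng"`).
#' @return `data` (blank rows dropped) with added columns
#'   `<value_col>_corrected`, `below_lod`, `negative_flag`, and the limits as
#'   attribute `"limits"`.
#' @export
blank_correct_samples <- function(data, blanks = NULL, value_col = "ce_ng") {
  if (!value_col %in% names(data))
    abort(sprintf("Column '%s' not found.", value_col),
          class = "alidose_input_error")
  if (is.null(blanks)) {
    if (!"compartment" %in% names(data) || !any(data$compartment == "blank"))
      abort("No blanks supplied and no compartment == 'blank' rows found.",
            class = "alidose_input_error")
    blanks <- data[[value_col]][data$compartment == "blank"]
    data <- data[data$compartment != "blank", ]
  }
  if (length(blanks) < 1L)
    abort("At least 1 blank is required.", class = "alidose_input_error")
  limits <- if (length(blanks) >= 2L) lod_loq(blanks) else
    tibble::tibble(lod = NA_real_, loq = NA_real_, n_blanks = 1L,
                   blank_mean = mean(blanks), blank_sd = NA_real_)
  corrected <- data[[value_col]] - limits$blank_mean
  data[[paste0(value_col, "_corrected")]] <- corrected
  data$below_lod <- if (is.na(limits$lod)) NA else corrected < limits$lod
  data$negative_flag <- corrected < 0
  attr(data, "limits") <- limits
  data
}

#' Recovery check against a reference material
#'
#' Recovery percentage `100 * measured / reference`; the method passes when
#' recovery lies within the validated band (inclusive bounds, default
#' 86-120%).
#'
#' @param measured,reference Measured and certified values (reference > 0).
#' @param bounds Length-2 acceptance band in percent.
#' @return Tibble: `recovery_pct`, `pass` (vectorised over `measured`).
#' @export
recovery_check <- function(measured, reference, bounds = c(86, 120)) {
  if (any(reference <= 0))
    abort("`reference` must be > 0.", class = "alidose_input_error")
  r <- 100 * measured / reference
  tibble::tibble(recovery_pct = r, pass = r >= bounds[1] & r <= bounds[2])
}

#' Deposition and uptake rates from compartment masses
#'
#' The deposited dose is the sum of the intracellular, wash and basal Ce
#' masses; rates divide by insert area and exposure time. The intracellular
#' fraction is cells / total (missing when the total is zero).
#'
#' @param cells_ng,wash_ng,basal_ng Compartment masses (ng), vectorised.
#' @param insert_area_cm2 Insert growth area (cm2, > 0; default 1.12).
#' @param exposure_time_h Exposure duration (h, > 0).
#' @return Tibble: `deposition_ng_cm2_h`, `uptake_ng_cm2_h`,
#'   `intracellular_fraction`.
#' @export
#' @examples
#' total_deposition(21.73, 8.535, 8.535, 1.12, 4) # 8.66, 4.85, 0.56
total_deposition <- function(cells_ng, wash_ng, basal_ng,
                             insert_area_cm2 = 1.12, exposure_time_h) {
  if (any(insert_area_cm2 <= 0) || any(exposure_time_h <= 0))
    abort("Area and exposure time must be > 0.", class = "alidose_input_error")
  total <- cells_ng + wash_ng + basal_ng
  denom <- insert_area_cm2 * exposure_time_h
  tibble::tibble(
    deposition_ng_cm2_h = total / denom,
    uptake_ng_cm2_h = cells_ng / denom,
    intracellular_fraction = ifelse(total == 0, NA_real_, cells_ng / total))
}

#' Per-insert deposition rates from a long ICP-MS table
#'
#' Blank-corrects a long compartment table (see [simulate_icpms_study()] for
#' the layout), spreads the cells/wash/basal masses per insert and timepoint,
#' and applies [total_deposition()].
#'
#' @param data Long tibble with `insert_id`, `timepoint_h`, `compartment`,
#'   `ce_ng` and blank rows (`compartment == "blank"`).
#' @param insert_area_cm2 Insert growth area (cm2).
#' @return Tibble with one row per insert: ids, compartment masses
#'   (blank-corrected) and the three rate/fraction columns.
#' @export
deposition_rates <- function(data, insert_area_cm2 = 1.12) {
  corrected <- blank_correct_samples(data)
  wide <- corrected |>
    dplyr::select("insert_id", "timepoint_h", "compartment",
                  "ce_ng_corrected") |>
    tidyr::pivot_wider(names_from = "compartment",
                       values_from = "ce_ng_corrected")
  for (nm in c("cells", "wash", "basal")) {
    if (!nm %in% names(wide))
      abort(sprintf("Compartment '%s' missing from the table.", nm),
            class = "alidose_input_error")
  }
  dplyr::bind_cols(
    wide,
    total_deposition(wide$cells, wide$wash, wide$basal,
                     insert_area_cm2 = insert_area_cm2,
                     exposure_time_h = wide$timepoint_h))
}
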