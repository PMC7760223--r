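# Readers and writers for the CSV dialects the instruments export and the
# pipeline emits. All readers return the same tibble layouts the generators
# produce, so simulated and real data flow through identical code.

#' Read a long-format plate-reader CSV
#'
#' Expected columns: `plate_id`, `date`, `condition`, `insert_id`,
#' `replicate`, `abs450`, `abs562` (one row per technical replicate).
#'
#' @param path CSV file path.
#' @return Tibble of plate readings.
#' @export
read_plate_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("plate_id", "condition", "insert_id", "abs450", "abs562")
  miss <- setdiff(required, names(df))
  if (length(miss))
    abort(paste0("Plate CSV lacks column(s): ", paste(miss, collapse = ", ")),
          class = "alidose_input_error")
  if ("date" %in% names(df)) df$date <- as.Date(df$date)
  df
}

#' Write viability records to CSV
#'
#' @param viability Tibble from [compute_viability()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_viability_csv <- function(viability, path) {
  readr::write_csv(viability, path)
  invisible(path)
}

#' Read SMPS scan exports
#'
#' Expected columns: `diameter_nm` and either `number_per_cm3` (counts per
#' bin) or `dndlogdp` (normalised concentration dN/dlogDp); an optional
#' `scan_id` column separates scans (a single scan is assumed otherwise).
#' dN/dlogDp exports are converted to per-bin counts by multiplying by each
#' bin's log10 width, estimated from the midpoint spacing.
#'
#' @param path CSV file path.
#' @return Tibble with `scan_id`, `diameter_nm`, `number_per_cm3`.
#' @export
read_smps_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"diameter_nm" %in% names(df))
    abort("SMPS CSV needs a diameter_nm column.", class = "alidose_input_error")
  if (!"scan_id" %in% names(df)) df$scan_id <- "scan_001"
  if (!"number_per_cm3" %in% names(df)) {
    if (!"dndlogdp" %in% names(df))
      abort("SMPS CSV needs number_per_cm3 or dndlogdp.",
            class = "alidose_input_error")
    df <- df |>
      dplyr::group_by(.data$scan_id) |>
      dplyr::arrange(.data$diameter_nm, .by_group = TRUE) |>
      dplyr::mutate(number_per_cm3 = .data$dndlogdp *
                      bin_log_widths(.data$diameter_nm)) |>
      dplyr::ungroup()
  }
  dplyr::select(df, "scan_id", "diameter_nm", "number_per_cm3")
}

# log10 bin widths from midpoints: geometric-mean edges between neighbours,
# end bins extended symmetrically.
bin_log_widths <- function(mid) {
  lg <- log10(mid)
  n <- length(lg)
  if (n == 1L) return(1)
  half <- diff(lg) / 2
  lower <- c(lg[1] - half[1], lg[-n] + half)
  upper <- c(lg[-n] + half, lg[n] + half[n - 1L])
  upper - lower
}

#' Read an ICP-MS result CSV
#'
#' Expected columns: `sample_id`, `insert_id`, `timepoint_h`, `compartment`
#' (`cells`/`wash`/`basal`/`blank`), `value`, `unit` (`ng` or `ng_ml`) and,
#' for concentrations, `volume_ml`. Concentrations are converted to masses
#' (`ce_ng = value * volume_ml * dilution_factor`) at ingest.
#'
#' @param path CSV file path.
#' @return Tibble in the layout of [simulate_icpms_study()].
#' @export
read_icpms_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("sample_id", "compartment", "value", "unit")
  miss <- setdiff(required, names(df))
  if (length(miss))
    abort(paste0("ICP-MS CSV lacks column(s): ", paste(miss, collapse = ", ")),
          class = "alidose_input_error")
  if (!"dilution_factor" %in% names(df)) df$dilution_factor <- 1
  if (any(df$dilution_factor < 1))
    abort("Dilution factors must be >= 1.", class = "alidose_input_error")
  df$ce_ng <- ifelse(df$unit == "ng", df$value * df$dilution_factor,
                     df$value * df$volume_ml * df$dilution_factor)
  if (any(!is.finite(df$ce_ng)))
    abort("Non-finite Ce mass after unit conversion (missing volume_ml?).",
          class = "alidose_input_error")
  df
}

#' Read a two-column ToF-SIMS spectrum file
#'
#' Whitespace- or comma-separated `m/z intensity` pairs, one channel per
#' line; lines starting with `#` are ignored.
#'
#' @param path Spectrum file path.
#' @param group,replicate_id Labels attached to the spectrum.
#' @return Tibble with `group`, `replicate_id`, `mz`, `intensity`.
#' @export
read_tofsims_txt <- function(path, group, replicate_id = basename(path)) {
  df <- utils::read.table(path, comment.char = "#", sep = "",
                          col.names = c("mz", "intensity"))
  tibble::tibble(group = group, replicate_id = replicate_id,
                 mz = df$mz, intensity = df$intensity)
}
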