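# SMPS number-size distributions -> aerosol mass concentration under the
# spherical-particle assumption, with the sub-50 nm exclusion policy and
# simple modality characterisation.

check_distribution <- function(dist) {
  if (!all(c("diameter_nm", "number_per_cm3") %in% names(dist)))
    abort("A size distribution needs columns diameter_nm and number_per_cm3.",
          class = "alidose_input_error")
  if (!nrow(dist))
    abort("Empty size distribution.", class = "alidose_input_error")
  if (any(dist$diameter_nm <= 0))
    abort("Diameters must be > 0.", class = "alidose_input_error")
  if (is.unsorted(dist$diameter_nm, strictly = TRUE))
    abort("Diameters must be strictly increasing.", class = "alidose_input_error")
  if (any(dist$number_per_cm3 < 0))
    abort("Negative number concentration.", class = "alidose_input_error")
  invisible(dist)
}

#' Aerosol mass concentration from a number-size distribution
#'
#' Assumes spherical particles of uniform bulk density: each bin contributes
#' `N_i * rho * pi/6 * d_i^3` with the bin midpoint as representative
#' diameter, and the sum is converted from g/cm3 of air to mg/m3 (factor
#' 1e9). The CeO2 default density is 7.3 g/cm3.
#'
#' @param dist Tibble with `diameter_nm` (strictly increasing) and
#'   `number_per_cm3` for one scan.
#' @param density Particle density, g/cm3.
#' @return Mass concentration in mg/m3 (scalar).
#' @export
#' @examples
#' mass_concentration(
#'   tibble::tibble(diameter_nm = 100, number_per_cm3 = 1000)) # 3.82e-3
mass_concentration <- function(dist, density = 7.3) {
  check_distribution(dist)
  if (density <= 0) abort("`density` must be > 0.", class = "alidose_input_error")
  d_cm <- dist$diameter_nm * 1e-7
  sum(dist$number_per_cm3 * density * pi / 6 * d_cm^3) * 1e9
}

#' Remove bins below a diameter cutoff
#'
#' Background-exclusion policy for aerosols whose sub-50 nm region is
#' dominated by a variable residual (e.g. dried solutes from the nebulised
#' water): bins with midpoints below the cutoff are dropped rather than
#' blank-subtracted. Mass never increases; applying the same cutoff twice is
#' a no-op.
#'
#' @param dist A size distribution (one scan or several, any extra columns
#'   kept).
#' @param cutoff_nm Diameter cutoff in nm (>= 0); bins strictly below it are
#'   removed.
#' @return The filtered tibble.
#' @export
apply_size_cutoff <- function(dist, cutoff_nm = 50) {
  if (cutoff_nm < 0) abort("`cutoff_nm` must be >= 0.", class = "alidose_input_error")
  dplyr::filter(dist, .data$diameter_nm >= cutoff_nm)
}

#' Detect modes of a size distribution
#'
#' Local maxima of the (optionally smoothed) number concentration against
#' diameter, interior bins only, returned in ascending diameter order. A
#' 3-bin moving average is applied by default; `window = 1` disables
#' smoothing.
#'
#' @param dist One scan's size distribution (>= 3 bins).
#' @param window Odd moving-average window in bins (default 3).
#' @return Numeric vector of mode diameters (nm); empty if none.
#' @export
detect_modes <- function(dist, window = 3L) {
  check_distribution(dist)
  if (nrow(dist) < 3L)
    abort("At least 3 bins are required.", class = "alidose_input_error")
  if (window %% 2L != 1L || window < 1L)
    abort("`window` must be a positive odd integer.", class = "alidose_input_error")
  y <- dist$number_per_cm3
  if (window > 1L) {
    sm <- stats::filter(y, rep(1 / window, window), sides = 2)
    y <- ifelse(is.na(sm), y, as.numeric(sm))
  }
  n <- length(y)
  i <- 2:(n - 1)
  is_mode <- y[i] > y[i - 1] & y[i] > y[i + 1]
  dist$diameter_nm[i][is_mode]
}

#' Mean aerosol mass over repeated scans
#'
#' Per-scan mass concentration (after an optional diameter cutoff), then mean
#' and sample standard deviation across scans — the summary an exposure run
#' reports as "C +/- sd mg/m3".
#'
#' @param scans Tibble of scans with `scan_id`, `diameter_nm`,
#'   `number_per_cm3`.
#' @param density Particle density, g/cm3.
#' @param cutoff_nm Optional diameter cutoff applied per scan before the mass
#'   computation (`NULL` = whole distribution).
#' @return One-row tibble: `n_scans`, `mean_mg_m3`, `sd_mg_m3`.
#' @export
mean_mass_over_scans <- function(scans, density = 7.3, cutoff_nm = NULL) {
  if (!"scan_id" %in% names(scans))
    abort("`scans` needs a scan_id column.", class = "alidose_input_error")
  masses <- scans |>
    dplyr::group_by(.data$scan_id) |>
    dplyr::group_map(function(df, key) {
      if (!is.null(cutoff_nm)) df <- apply_size_cutoff(df, cutoff_nm)
      if (!nrow(df)) return(0)
      mass_concentration(df, density = density)
    }) |>
    unlist()
  tibble::tibble(n_scans = length(masses), mean_mg_m3 = mean(masses),
                 sd_mg_m3 = if (length(masses) > 1) sd(masses) else 0)
}
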