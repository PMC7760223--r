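# Seeded generators for every input the pipeline consumes. One global seed in
# the config; each generator derives an independent stream by a fixed offset so
# that adding scans never perturbs the plate data and vice versa.

seed_offsets <- c(plates = 101L, smps = 202L, icpms = 303L, tofsims = 404L)

with_sim_seed <- function(cfg, stream, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(cfg$seed + seed_offsets[[stream]])
  force(code)
}

#' Simulate WST-1 plate-reader absorbance tables
#'
#' Draws per-well dual-wavelength absorbances for a multi-plate, multi-day
#' viability study. Noise is Gaussian on absorbance, not on viability: each
#' insert's 450 nm absorbance is Normal around its condition mean with relative
#' sd `well_cov`, technical replicates add Normal pipetting noise with relative
#' sd `technical_cov`, and a plate-level random effect (sd `plate_effect_sd`,
#' in % viability units) shifts the exposure-condition means while the
#' incubator control and the medium blank stay put, so the control defines
#' 100% on every plate. The 562 nm channel, which lies outside the formazan
#' absorption spectrum and exists only to catch optical interferences, is a
#' low constant plus noise. Blank wells sit at `blank_fraction` of the control
#' mean.
#'
#' @param config An [ali_sim_config()].
#' @return A tibble with one row per technical replicate: `plate_id`, `date`,
#'   `condition`, `insert_id`, `replicate`, `abs450`, `abs562`.
#' @export
#' @examples
#' head(simulate_plate_readings(ali_sim_config(seed = 1)))
simulate_plate_readings <- function(config) {
  stopifnot(inherits(config, "ali_sim_config"))
  cfg <- config
  with_sim_seed(cfg, "plates", {
    ctrl <- cfg$control_absorbance_mean
    blank_abs <- cfg$blank_fraction * ctrl
    conds <- c(incubator_control = 100, cfg$condition_truths)
    rows <- purrr::map_dfr(seq_len(cfg$n_plates), function(p) {
      plate_effect <- rnorm(1, 0, cfg$plate_effect_sd)
      per_cond <- purrr::imap_dfr(conds, function(truth, cond) {
        shifted <- if (cond == "incubator_control") truth else truth + plate_effect
        mean_abs <- blank_abs + (shifted / 100) * (ctrl - blank_abs)
        insert_true <- rnorm(cfg$wells_per_condition, mean_abs,
                             cfg$well_cov * abs(mean_abs))
        sim_insert_rows(cfg, cond, insert_true)
      })
      blank_true <- rnorm(cfg$wells_per_condition, blank_abs,
                          cfg$blank_cov * blank_abs)
      per_blank <- sim_insert_rows(cfg, "medium_blank", blank_true)
      out <- dplyr::bind_rows(per_cond, per_blank)
      out$plate_id <- sprintf("plate_%02d", p)
      out$date <- as.Date("2026-01-05") + (p - 1L) * 7L
      out
    })
    dplyr::select(rows, "plate_id", "date", "condition", "insert_id",
                  "replicate", "abs450", "abs562")
  })
}

sim_insert_rows <- function(cfg, cond, insert_true) {
  nrep <- cfg$technical_reps_per_well
  purrr::map_dfr(seq_along(insert_true), function(i) {
    reps <- rnorm(nrep, insert_true[i], cfg$technical_cov * abs(insert_true[i]))
    tibble::tibble(
      condition = cond,
      insert_id = sprintf("%s_ins%02d", cond, i),
      replicate = seq_len(nrep),
      abs450 = pmax(reps, 0),
      abs562 = pmax(rnorm(nrep, 0.04, 0.005), 0))
  })
}

# Shared log-spaced SMPS bin grid: 64 bins spanning 10-1000 nm.
smps_bin_grid <- function(n_bins = 64L, d_min = 10, d_max = 1000) {
  if (n_bins < 1L) abort("Empty bin grid.", class = "alidose_config_error")
  edges <- 10^seq(log10(d_min), log10(d_max), length.out = n_bins + 1L)
  list(lower = edges[-(n_bins + 1L)], upper = edges[-1L],
       mid = sqrt(edges[-(n_bins + 1L)] * edges[-1L]))
}

#' Simulate SMPS number-size-distribution scans
#'
#' Bin counts on a fixed 64-bin log-spaced grid (10-1000 nm) are the sum over
#' the configured lognormal modes of each mode's bin probability mass times its
#' total number concentration, multiplied by one lognormal scan-to-scan factor
#' (geometric sd `scan_gsd`) that emulates day-to-day aerosol variability.
#'
#' @param config An [ali_sim_config()].
#' @param n_bins,d_min,d_max Bin grid (defaults: 64 log-spaced bins, 10-1000 nm).
#' @return A tibble with `scan_id`, `diameter_nm` (bin midpoints, strictly
#'   increasing within a scan) and `number_per_cm3`.
#' @export
simulate_smps_scans <- function(config, n_bins = 64L, d_min = 10, d_max = 1000) {
  stopifnot(inherits(config, "ali_sim_config"))
  cfg <- config
  grid <- smps_bin_grid(n_bins, d_min, d_max)
  base <- rowSums(vapply(cfg$aerosol_modes, function(m) {
    m$total_number * (plnorm(grid$upper, log(m$gmd_nm), log(m$gsd)) -
                        plnorm(grid$lower, log(m$gmd_nm), log(m$gsd)))
  }, numeric(length(grid$mid))))
  with_sim_seed(cfg, "smps", {
    purrr::map_dfr(seq_len(cfg$n_smps_scans), function(s) {
      f <- exp(rnorm(1, 0, log(cfg$scan_gsd)))
      tibble::tibble(scan_id = sprintf("scan_%03d", s),
                     diameter_nm = grid$mid,
                     number_per_cm3 = base * f)
    })
  })
}

#' Simulate an ICP-MS compartment study
#'
#' Emits six blank digests plus, for every insert and exposure duration, the
#' Ce mass found intracellularly, in the wash solution and in the basal
#' medium. The expected blank-corrected compartment sum per area per hour is
#' `uptake_rate_true / intracellular_fraction_true`, the cells' share of the
#' total is `intracellular_fraction_true`, and the remainder splits evenly
#' between wash and basal. Each measurement is the true mass times a
#' multiplicative Gaussian error (relative sd `icpms_measurement_cov`) plus a
#' Gaussian blank background.
#'
#' @param config An [ali_sim_config()].
#' @param n_blanks Number of blank digests (default 6).
#' @return A tibble with `sample_id`, `insert_id`, `timepoint_h`,
#'   `compartment` (`cells`/`wash`/`basal`/`blank`), `ce_ng`,
#'   `dilution_factor`.
#' @export
simulate_icpms_study <- function(config, n_blanks = 6L) {
  stopifnot(inherits(config, "ali_sim_config"))
  cfg <- config
  with_sim_seed(cfg, "icpms", {
    blanks <- tibble::tibble(
      sample_id = sprintf("blank_%d", seq_len(n_blanks)),
      insert_id = NA_character_, timepoint_h = NA_real_,
      compartment = "blank",
      ce_ng = rnorm(n_blanks, cfg$icpms_blank_mean, cfg$icpms_blank_sd),
      dilution_factor = 1)
    frac <- cfg$intracellular_fraction_true
    design <- tidyr::expand_grid(timepoint_h = cfg$timepoints_h,
                                 insert = seq_len(cfg$inserts_per_timepoint))
    samples <- purrr::pmap_dfr(design, function(timepoint_h, insert) {
      total <- if (frac > 0) {
        cfg$uptake_rate_true / frac * cfg$insert_area_cm2 * timepoint_h
      } else 0
      true <- c(cells = frac * total,
                wash = (1 - frac) * total / 2,
                basal = (1 - frac) * total / 2)
      measured <- unname(true * (1 + rnorm(3, 0, cfg$icpms_measurement_cov)) +
                           rnorm(3, cfg$icpms_blank_mean, cfg$icpms_blank_sd))
      insert_id <- sprintf("t%gh_ins%02d", timepoint_h, insert)
      tibble::tibble(sample_id = paste0(insert_id, "_", names(true)),
                     insert_id = insert_id, timepoint_h = timepoint_h,
                     compartment = names(true), ce_ng = measured,
                     dilution_factor = 1)
    })
    dplyr::bind_rows(blanks, samples)
  })
}

#' Simulate ToF-SIMS replicate spectra
#'
#' For each configured group, draws `spectra_per_group` spectra whose channel
#' intensities are Normal around the group's peak means (truncated at zero).
#' Channels are emitted at the configured fractional m/z positions so that
#' unit-mass binning is exercised downstream.
#'
#' @param config An [ali_sim_config()].
#' @return A tibble with `group`, `replicate_id`, `mz`, `intensity`.
#' @export
simulate_tofsims_spectra <- function(config) {
  stopifnot(inherits(config, "ali_sim_config"))
  cfg <- config
  if (length(cfg$spectra_groups) < 1L)
    abort("At least one spectra group is required.", class = "alidose_config_error")
  with_sim_seed(cfg, "tofsims", {
    purrr::imap_dfr(cfg$spectra_groups, function(peaks, grp) {
      purrr::map_dfr(seq_len(cfg$spectra_per_group), function(r) {
        tibble::tibble(
          group = grp,
          replicate_id = sprintf("%s_rep%d", grp, r),
          mz = peaks$mz,
          intensity = pmax(rnorm(nrow(peaks), peaks$mean, peaks$sd), 0))
      })
    })
  })
}
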