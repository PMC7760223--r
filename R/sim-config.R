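#' Simulation configuration for the synthetic ALI study
#'
#' Bundles every knob of the synthetic-data generators into a single validated
#' object. The defaults reproduce the statistical structure of the study the
#' package models: three plates run on different days, three inserts per
#' condition, three technical replicates per insert, ~12% well-to-well
#' coefficient of variation on control absorbance, a medium blank at ~3% of the
#' control signal, a bimodal aerosol (residual mode near 20 nm plus a particle
#' mode near 90 nm) whose analytic mass concentration is ~1.07 mg/m3 for the
#' whole distribution and ~1.03 mg/m3 above 50 nm, an ICP-MS compartment split
#' with 56% of the deposited dose intracellular, and two ToF-SIMS groups whose
#' high-mass lipid ions are depressed after exposure.
#'
#' @param seed Integer seed; every generator derives its own stream from it by
#'   a fixed offset, so a fixed seed gives byte-identical outputs.
#' @param n_plates Number of plates (one plate per calendar day).
#' @param wells_per_condition Inserts per condition on each plate.
#' @param technical_reps_per_well Technical replicates pipetted per insert.
#' @param condition_truths Named numeric vector of true mean viabilities (% of
#'   the incubator control) for the exposure conditions. The incubator control
#'   (truth 100%) and the medium blank are always generated in addition.
#' @param well_cov Relative sd of insert-level absorbance around its condition
#'   mean (fraction; default 0.12).
#' @param blank_cov Relative sd of blank-well absorbance (default 0.075).
#' @param technical_cov Relative sd of technical replicates around their
#'   insert's absorbance (pipetting noise; default 0.02).
#' @param plate_effect_sd Between-plate sd of condition means, in % viability
#'   units; applied to exposure conditions only so that the incubator control
#'   defines 100% on every plate.
#' @param blank_fraction Medium-blank absorbance as a fraction of the control
#'   mean (default 0.03).
#' @param control_absorbance_mean Mean 450 nm absorbance of the incubator
#'   control, in AU.
#' @param aerosol_modes List of lognormal aerosol modes, each a list with
#'   `gmd_nm` (geometric mean diameter, nm), `gsd` (> 1) and `total_number`
#'   (total number concentration, particles/cm3).
#' @param n_smps_scans Number of SMPS scans to simulate.
#' @param scan_gsd Geometric sd of the per-scan multiplicative noise factor.
#' @param particle_density Bulk particle density in g/cm3 (CeO2: 7.3).
#' @param icpms_blank_mean,icpms_blank_sd Mean and sd of the Ce background in
#'   blank digests (ng).
#' @param icpms_measurement_cov Relative sd of the ICP-MS measurement around
#'   the true compartment mass.
#' @param uptake_rate_true True intracellular uptake rate, ng cm^-2 h^-1.
#' @param intracellular_fraction_true True fraction of the deposited dose that
#'   is intracellular (the remainder splits evenly between wash and basal).
#' @param insert_area_cm2 Insert growth area (cm2).
#' @param timepoints_h Exposure durations (h) at which inserts are harvested.
#' @param inserts_per_timepoint Inserts per exposure duration.
#' @param spectra_per_group ToF-SIMS replicate spectra per group (default 6).
#' @param spectra_groups Named list of per-group peak tables, each a data frame
#'   with columns `mz`, `mean`, `sd`. See [default_spectra_groups()].
#'
#' @return An object of class `ali_sim_config` (a validated list).
#' @seealso [simulate_plate_readings()], [simulate_smps_scans()],
#'   [simulate_icpms_study()], [simulate_tofsims_spectra()]
#' @export
#' @examples
#' cfg <- ali_sim_config(seed = 7, n_plates = 3)
#' cfg$well_cov
ali_sim_config <- function(seed = 1L,
                           n_plates = 3L,
                           wells_per_condition = 3L,
                           technical_reps_per_well = 3L,
                           condition_truths = c(air_1ml_min = 97,
                                                air_5ml_min = 86,
                                                air_10ml_min = 39,
                                                positive_control = 1),
                           well_cov = 0.12,
                           blank_cov = 0.075,
                           technical_cov = 0.02,
                           plate_effect_sd = 5,
                           blank_fraction = 0.03,
                           control_absorbance_mean = 1.0,
                           aerosol_modes = list(
                             list(gmd_nm = 20, gsd = 1.4, total_number = 7.4e5),
                             list(gmd_nm = 90, gsd = 1.6, total_number = 1.37e5)),
                           n_smps_scans = 20L,
                           scan_gsd = 1.1,
                           particle_density = 7.3,
                           icpms_blank_mean = 0.2,
                           icpms_blank_sd = 0.05,
                           icpms_measurement_cov = 0.3,
                           uptake_rate_true = 4.85,
                           intracellular_fraction_true = 0.56,
                           insert_area_cm2 = 1.12,
                           timepoints_h = c(1, 2, 4),
                           inserts_per_timepoint = 3L,
                           spectra_per_group = 6L,
                           spectra_groups = default_spectra_groups()) {
  cfg <- list(seed = as.integer(seed), n_plates = as.integer(n_plates),
              wells_per_condition = as.integer(wells_per_condition),
              technical_reps_per_well = as.integer(technical_reps_per_well),
              condition_truths = condition_truths, well_cov = well_cov,
              blank_cov = blank_cov, technical_cov = technical_cov,
              plate_effect_sd = plate_effect_sd,
              blank_fraction = blank_fraction,
              control_absorbance_mean = control_absorbance_mean,
              aerosol_modes = aerosol_modes, n_smps_scans = as.integer(n_smps_scans),
              scan_gsd = scan_gsd, particle_density = particle_density,
              icpms_blank_mean = icpms_blank_mean, icpms_blank_sd = icpms_blank_sd,
              icpms_measurement_cov = icpms_measurement_cov,
              uptake_rate_true = uptake_rate_true,
              intracellular_fraction_true = intracellular_fraction_true,
              insert_area_cm2 = insert_area_cm2, timepoints_h = timepoints_h,
              inserts_per_timepoint = as.integer(inserts_per_timepoint),
              spectra_per_group = as.integer(spectra_per_group),
              spectra_groups = spectra_groups)
  validate_sim_config(cfg)
  structure(cfg, class = "ali_sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_plates", "wells_per_condition", "technical_reps_per_well",
              "n_smps_scans", "inserts_per_timepoint", "spectra_per_group")
  for (nm in counts) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 1L)
      abort(sprintf("`%s` must be a positive count, got %s.", nm, cfg[[nm]]),
            class = "alidose_config_error")
  }
  nonneg <- c("well_cov", "blank_cov", "technical_cov", "plate_effect_sd",
              "icpms_blank_sd", "icpms_measurement_cov", "uptake_rate_true")
  for (nm in nonneg) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 0)
      abort(sprintf("`%s` must be >= 0.", nm), class = "alidose_config_error")
  }
  if (any(!is.finite(cfg$condition_truths)) || any(cfg$condition_truths < 0))
    abort("`condition_truths` must be finite and >= 0.",
          class = "alidose_config_error")
  if (is.null(names(cfg$condition_truths)) || any(names(cfg$condition_truths) == ""))
    abort("`condition_truths` must be a named vector.",
          class = "alidose_config_error")
  if (cfg$blank_fraction < 0 || cfg$blank_fraction >= 1)
    abort("`blank_fraction` must be in [0, 1).", class = "alidose_config_error")
  if (cfg$control_absorbance_mean <= 0)
    abort("`control_absorbance_mean` must be > 0.", class = "alidose_config_error")
  if (length(cfg$aerosol_modes) < 1L)
    abort("At least one aerosol mode is required.", class = "alidose_config_error")
  for (m in cfg$aerosol_modes) {
    if (m$gmd_nm <= 0 || m$gsd <= 1 || m$total_number < 0)
      abort("Each aerosol mode needs gmd_nm > 0, gsd > 1 and total_number >= 0.",
            class = "alidose_config_error")
  }
  if (cfg$scan_gsd < 1)
    abort("`scan_gsd` must be >= 1.", class = "alidose_config_error")
  if (cfg$particle_density <= 0)
    abort("`particle_density` must be > 0.", class = "alidose_config_error")
  if (cfg$intracellular_fraction_true < 0 || cfg$intracellular_fraction_true > 1)
    abort("`intracellular_fraction_true` must be in [0, 1].",
          class = "alidose_config_error")
  if (cfg$insert_area_cm2 <= 0 || any(cfg$timepoints_h <= 0))
    abort("Insert area and timepoints must be > 0.", class = "alidose_config_error")
  invisible(cfg)
}

#' Default ToF-SIMS group peak tables
#'
#' Two groups of positive-ion spectra: unexposed controls and cells after 4 h
#' of aerosol exposure. The peak list covers a cholesterol-region ion and
#' phospholipid/ceramide ions in the 600-820 u range; in the exposed group the
#' lipid ions at nominal masses 625, 777, 791 and 813 u are depressed to
#' roughly half the control level, emulating the down-regulated
#' phosphatidylcholine / phosphatidylethanolamine / ceramide signals such
#' experiments report. Fractional m/z values exercise unit-mass binning.
#'
#' @return Named list of data frames with columns `mz`, `mean`, `sd`.
#' @export
default_spectra_groups <- function() {
  mz <- c(369.35, 496.34, 551.50, 625.51, 777.55, 791.58, 813.59)
  control <- data.frame(
    mz = mz,
    mean = c(100, 60, 40, 30, 25, 50, 35),
    sd = c(8, 6, 5, 4, 3, 5, 4))
  exposed <- control
  lipid <- control$mz %in% c(625.51, 777.55, 791.58, 813.59)
  exposed$mean[lipid] <- control$mean[lipid] * c(0.50, 0.55, 0.50, 0.60)
  exposed$sd[lipid] <- control$sd[lipid] * 0.6
  list(control = control, exposed_4h = exposed)
}

#' @export
print.ali_sim_config <- function(x, ...) {
  cat("<ali_sim_config>\n")
  cat("  seed:", x$seed, " plates:", x$n_plates,
      " inserts/condition:", x$wells_per_condition, "\n")
  cat("  conditions:", paste(sprintf("%s=%g%%", names(x$condition_truths),
                                     x$condition_truths), collapse = ", "), "\n")
  cat("  well COV:", x$well_cov, " blank fraction:", x$blank_fraction, "\n")
  cat("  aerosol modes:",
      paste(vapply(x$aerosol_modes, function(m)
        sprintf("%gnm/GSD%g/%.3g cm-3", m$gmd_nm, m$gsd, m$total_number),
        character(1)), collapse = " + "), "\n")
  invisible(x)
}
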