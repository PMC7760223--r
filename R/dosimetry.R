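# Dose arithmetic for flow-through ALI exposure: theoretical maximum
# deposition, deposition efficiency, in vivo reference rate, in vitro / in
# vivo equivalence and particle surface-coverage fraction.
#
# Canonical internal units: masses in ng, areas in cm2, times in h, flows in
# mL/min, aerosol concentrations in mg/m3 (note 1 mg/m3 == 1 ng/mL).

#' Theoretical maximum deposition rate
#'
#' If every particle carried to the insert deposited, the areal mass rate
#' would be `concentration x flow / area`: with the aerosol concentration in
#' mg/m3 (= ng/mL) and the flow in mL/min, the rate is
#' `C * flow * 60 / area` ng cm^-2 h^-1, reported in ug cm^-2 h^-1.
#'
#' @param aerosol_mg_m3 Aerosol mass concentration (mg/m3).
#' @param flow_ml_min Flow rate per insert (mL/min; default 5).
#' @param insert_area_cm2 Insert growth area (cm2; default 1.12).
#' @return Maximum deposition rate in ug cm^-2 h^-1 (vectorised).
#' @export
#' @examples
#' maximum_deposition(1.07) # ~0.29 ug cm^-2 h^-1
maximum_deposition <- function(aerosol_mg_m3, flow_ml_min = 5,
                               insert_area_cm2 = 1.12) {
  if (any(aerosol_mg_m3 < 0) || any(flow_ml_min <= 0) || any(insert_area_cm2 <= 0))
    abort("Concentration must be >= 0; flow and area > 0.",
          class = "alidose_input_error")
  aerosol_mg_m3 * flow_ml_min * 60 / insert_area_cm2 / 1000
}

#' Deposition efficiency
#'
#' Measured areal deposition rate as a percentage of the theoretical maximum.
#' The measured rate is in ng cm^-2 h^-1 (how ICP-MS reports it) and the
#' maximum in ug cm^-2 h^-1 (how the aerosol arithmetic reports it); units
#' are harmonised internally.
#'
#' @param measured_ng_cm2_h Measured deposition rate (ng cm^-2 h^-1).
#' @param maximum_ug_cm2_h Maximum deposition rate (ug cm^-2 h^-1, > 0).
#' @return Efficiency in percent (vectorised).
#' @export
#' @examples
#' deposition_efficiency(8.66, maximum_deposition(1.07)) # ~3.0%
deposition_efficiency <- function(measured_ng_cm2_h, maximum_ug_cm2_h) {
  if (any(maximum_ug_cm2_h <= 0))
    abort("Maximum deposition must be > 0.", class = "alidose_input_error")
  100 * measured_ng_cm2_h / (maximum_ug_cm2_h * 1000)
}

#' In vivo reference uptake rate
#'
#' Converts a whole-lung burden from an inhalation study into an areal rate
#' comparable to the in vitro numbers: burden (ug -> ng) divided by alveolar
#' surface area and exposure duration.
#'
#' @param lung_burden_ug Deposited lung burden (ug).
#' @param alveolar_area_cm2 Alveolar surface area (cm2; rat ~4584).
#' @param exposure_h Cumulative exposure duration (h).
#' @return Rate in ng cm^-2 h^-1.
#' @export
#' @examples
#' in_vivo_reference_rate(2620, 4584, 120) # 4.76
in_vivo_reference_rate <- function(lung_burden_ug, alveolar_area_cm2,
                                   exposure_h) {
  if (any(lung_burden_ug < 0) || any(alveolar_area_cm2 <= 0) ||
      any(exposure_h <= 0))
    abort("Burden must be >= 0; area and duration > 0.",
          class = "alidose_input_error")
  lung_burden_ug * 1000 / alveolar_area_cm2 / exposure_h
}

#' Compare in vitro and in vivo dose rates
#'
#' Ratio of the in vitro intracellular uptake rate to the in vivo reference
#' rate; the two are marked comparable when the ratio falls inside a
#' configurable band (default within a factor of two either way).
#'
#' @param in_vitro_ng_cm2_h,in_vivo_ng_cm2_h Rates in ng cm^-2 h^-1
#'   (in vivo > 0).
#' @param band Length-2 comparability band on the ratio (default c(0.5, 2)).
#' @return Tibble: `ratio`, `comparable`.
#' @export
compare_in_vitro_in_vivo <- function(in_vitro_ng_cm2_h, in_vivo_ng_cm2_h,
                                     band = c(0.5, 2)) {
  if (any(in_vivo_ng_cm2_h <= 0))
    abort("In vivo rate must be > 0.", class = "alidose_input_error")
  ratio <- in_vitro_ng_cm2_h / in_vivo_ng_cm2_h
  tibble::tibble(ratio = ratio,
                 comparable = ratio >= band[1] & ratio <= band[2])
}

#' Fraction of the cell surface covered by particles
#'
#' Projected-area monolayer model: an areal mass `m` of spheres of diameter
#' `d` and density `rho` corresponds to `m / (rho pi/6 d^3)` particles per
#' unit area, each shadowing `pi/4 d^2`, giving a covered fraction of
#' `1.5 m / (rho d)`. With the ~35 ng/cm2 dose of a 4 h exposure and 90 nm
#' particles this is of order 1e-3, i.e. the cell surface is essentially
#' uncovered.
#'
#' @param areal_dose_ng_cm2 Deposited areal mass (ng/cm2).
#' @param diameter_nm Particle diameter (nm; default the 90 nm principal
#'   aerosol mode).
#' @param density Particle density (g/cm3).
#' @return Dimensionless covered fraction (vectorised).
#' @export
#' @examples
#' coverage_fraction(8.66 * 4, 90, 7.3) # ~7.9e-4
coverage_fraction <- function(areal_dose_ng_cm2, diameter_nm = 90,
                              density = 7.3) {
  if (any(diameter_nm <= 0) || any(density <= 0))
    abort("Diameter and density must be > 0.", class = "alidose_input_error")
  if (any(areal_dose_ng_cm2 < 0))
    abort("Areal dose must be >= 0.", class = "alidose_input_error")
  1.5 * (areal_dose_ng_cm2 * 1e-9) / (density * diameter_nm * 1e-7)
}

#' Assemble a full dose report
#'
#' One-stop arithmetic combining the aerosol summary, the measured ICP-MS
#' rates and an in vivo reference into the quantities an exposure run
#' reports.
#'
#' @param aerosol_mg_m3 Mean aerosol mass concentration (mg/m3).
#' @param measured_ng_cm2_h Measured deposition rate (ng cm^-2 h^-1).
#' @param uptake_ng_cm2_h Intracellular uptake rate (ng cm^-2 h^-1).
#' @param flow_ml_min,insert_area_cm2 Exposure configuration.
#' @param exposure_time_h Exposure duration (h), for the total dose and the
#'   coverage fraction.
#' @param lung_burden_ug,alveolar_area_cm2,in_vivo_exposure_h In vivo
#'   reference (defaults: 2620 ug over 4584 cm2 in 120 h).
#' @param particle_diameter_nm,density Particle geometry for the coverage
#'   fraction.
#' @return One-row tibble with `max_deposition_ug_cm2_h`,
#'   `measured_ng_cm2_h`, `efficiency_pct`, `uptake_ng_cm2_h`,
#'   `in_vivo_ng_cm2_h`, `in_vitro_in_vivo_ratio`, `comparable`,
#'   `coverage_fraction`.
#' @export
dose_report <- function(aerosol_mg_m3, measured_ng_cm2_h, uptake_ng_cm2_h,
                        flow_ml_min = 5, insert_area_cm2 = 1.12,
                        exposure_time_h = 4, lung_burden_ug = 2620,
                        alveolar_area_cm2 = 4584, in_vivo_exposure_h = 120,
                        particle_diameter_nm = 90, density = 7.3) {
  max_rate <- maximum_deposition(aerosol_mg_m3, flow_ml_min, insert_area_cm2)
  eff <- deposition_efficiency(measured_ng_cm2_h, max_rate)
  in_vivo <- in_vivo_reference_rate(lung_burden_ug, alveolar_area_cm2,
                                    in_vivo_exposure_h)
  cmp <- compare_in_vitro_in_vivo(uptake_ng_cm2_h, in_vivo)
  tibble::tibble(
    max_deposition_ug_cm2_h = max_rate,
    measured_ng_cm2_h = measured_ng_cm2_h,
    efficiency_pct = eff,
    uptake_ng_cm2_h = uptake_ng_cm2_h,
    in_vivo_ng_cm2_h = in_vivo,
    in_vitro_in_vivo_ratio = cmp$ratio,
    comparable = cmp$comparable,
    coverage_fraction = coverage_fraction(
      measured_ng_cm2_h * exposure_time_h, particle_diameter_nm, density))
}
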