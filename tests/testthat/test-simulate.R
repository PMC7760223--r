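test_that("all generators are byte-identical under a fixed seed", {
  cfg <- ali_sim_config(seed = 7)
  expect_identical(simulate_plate_readings(cfg), simulate_plate_readings(cfg))
  expect_identical(simulate_smps_scans(cfg), simulate_smps_scans(cfg))
  expect_identical(simulate_icpms_study(cfg), simulate_icpms_study(cfg))
  expect_identical(simulate_tofsims_spectra(cfg),
                   simulate_tofsims_spectra(cfg))
  # and differ under a different seed
  cfg2 <- ali_sim_config(seed = 8)
  expect_false(identical(simulate_plate_readings(cfg),
                         simulate_plate_readings(cfg2)))
})

test_that("zero-noise plates give exactly 100% viability at truth 100", {
  cfg <- noise_free_config(truths = c(test = 100))
  v <- compute_viability(simulate_plate_readings(cfg))
  nonblank <- v[v$condition != "medium_blank", ]
  expect_equal(nonblank$viability_pct, rep(100, nrow(nonblank)),
               tolerance = 1e-12)
})

test_that("generated wells recover the configured truth and COV (moments)", {
  cfg <- ali_sim_config(seed = 11, n_plates = 1, wells_per_condition = 200,
                        technical_reps_per_well = 1, technical_cov = 0,
                        plate_effect_sd = 0,
                        condition_truths = c(test = 85))
  r <- simulate_plate_readings(cfg)
  v <- compute_viability(r)
  test_v <- v$viability_pct[v$condition == "test"]
  se <- sd(test_v) / sqrt(length(test_v))
  expect_lt(abs(mean(test_v) - 85), 3 * se)
  abs_test <- r$abs450[r$condition == "test"]
  cov_hat <- sd(abs_test) / mean(abs_test)
  expect_gt(cov_hat, 0.09)
  expect_lt(cov_hat, 0.15)
})

test_that("configuration invariants are enforced", {
  expect_error(ali_sim_config(n_plates = 0), class = "alidose_config_error")
  expect_error(ali_sim_config(well_cov = -0.1), class = "alidose_config_error")
  expect_error(ali_sim_config(condition_truths = c(a = -5)),
               class = "alidose_config_error")
  expect_error(ali_sim_config(aerosol_modes = list(
    list(gmd_nm = 90, gsd = 0.9, total_number = 1))),
    class = "alidose_config_error")
  expect_error(ali_sim_config(aerosol_modes = list()),
               class = "alidose_config_error")
})

test_that("a single-mode aerosol peaks within one bin of the analytic argmax", {
  cfg <- ali_sim_config(seed = 3, aerosol_modes = list(
    list(gmd_nm = 90, gsd = 1.6, total_number = 1e5)), n_smps_scans = 1)
  scan <- simulate_smps_scans(cfg)
  # independent oracle: analytic lognormal probability mass on the same grid
  edges <- 10^seq(log10(10), log10(1000), length.out = 65)
  pm <- plnorm(edges[-1], log(90), log(1.6)) -
    plnorm(edges[-65], log(90), log(1.6))
  oracle_mode <- sqrt(edges[-65] * edges[-1])[which.max(pm)]
  modes <- detect_modes(scan[, c("diameter_nm", "number_per_cm3")])
  expect_length(modes, 1)
  idx_got <- match(modes, scan$diameter_nm)
  idx_oracle <- match(oracle_mode, scan$diameter_nm)
  expect_lte(abs(idx_got - idx_oracle), 1)
})

test_that("the default bimodal aerosol shows maxima near 20 and 90 nm", {
  cfg <- ali_sim_config(seed = 4, n_smps_scans = 1)
  scan <- simulate_smps_scans(cfg)
  modes <- detect_modes(scan[, c("diameter_nm", "number_per_cm3")])
  expect_length(modes, 2)
  expect_lt(abs(log(modes[1] / 20)), log(1.3))
  expect_lt(abs(log(modes[2] / 90)), log(1.3))
})

test_that("zero total number concentration gives all-zero scans", {
  cfg <- ali_sim_config(seed = 5, aerosol_modes = list(
    list(gmd_nm = 90, gsd = 1.6, total_number = 0)), n_smps_scans = 2)
  scan <- simulate_smps_scans(cfg)
  expect_true(all(scan$number_per_cm3 == 0))
})

test_that("scans integrate to the configured mode totals within noise", {
  cfg <- ali_sim_config(seed = 6, n_smps_scans = 40)
  scans <- simulate_smps_scans(cfg)
  configured <- sum(vapply(cfg$aerosol_modes, `[[`, numeric(1),
                           "total_number"))
  totals <- tapply(scans$number_per_cm3, scans$scan_id, sum)
  # grid truncation loses a sliver of each mode; scan factor has GSD 1.1
  expect_lt(abs(mean(totals) / configured - 1), 0.10)
})

test_that("noise-free ICP-MS study partitions mass exactly", {
  cfg <- ali_sim_config(seed = 9, icpms_blank_mean = 0, icpms_blank_sd = 0,
                        icpms_measurement_cov = 0,
                        intracellular_fraction_true = 0.5)
  s <- simulate_icpms_study(cfg)
  wide <- tidyr::pivot_wider(
    s[s$compartment != "blank", c("insert_id", "compartment", "ce_ng")],
    names_from = "compartment", values_from = "ce_ng")
  expect_equal(wide$cells, wide$wash + wide$basal, tolerance = 1e-12)
})

test_that("noise-free ICP-MS cells mass matches hand arithmetic", {
  cfg <- ali_sim_config(seed = 9, icpms_blank_mean = 0, icpms_blank_sd = 0,
                        icpms_measurement_cov = 0, uptake_rate_true = 4.85,
                        intracellular_fraction_true = 0.56,
                        insert_area_cm2 = 1.12, timepoints_h = 4)
  s <- simulate_icpms_study(cfg)
  cells <- unname(s$ce_ng[s$compartment == "cells"])
  expect_equal(cells, rep(4.85 * 4 * 1.12, length(cells)), tolerance = 1e-12)
})
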