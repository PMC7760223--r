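# Shared fixtures, built in code.

quick_spec <- function(seed = 1L, n_iterations = 800L, ...) {
  consensus_model_spec(n_iterations = n_iterations, seed = seed, ...)
}

noise_free_config <- function(seed = 1L, truths = c(test = 100)) {
  ali_sim_config(seed = seed, condition_truths = truths, well_cov = 0,
                 blank_cov = 0, technical_cov = 0, plate_effect_sd = 0)
}

# Per-particle brute-force mass oracle: every particle's sphere mass summed
# one bin at a time, independent of the vectorised implementation.
mass_oracle <- function(diameter_nm, number_per_cm3, density) {
  total_g <- 0
  for (i in seq_along(diameter_nm)) {
    one <- density * pi / 6 * (diameter_nm[i] * 1e-7)^3
    total_g <- total_g + number_per_cm3[i] * one
  }
  total_g * 1e9
}

# A small already-binned spectra table: two groups, `n` spectra each, optional
# group shift on one bin plus Gaussian noise.
make_binned <- function(n = 6, bins = c(300L, 400L, 500L), shift_bin = 400L,
                        shift = 0, noise_sd = 1, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(c("control", "exposed"), function(g) {
    purrr::map_dfr(seq_len(n), function(r) {
      base <- c(40, 30, 30)
      if (g == "exposed") base[bins == shift_bin] <- base[bins == shift_bin] + shift
      tibble::tibble(group = g, replicate_id = paste0(g, "_", r),
                     mass_u = bins,
                     intensity_pct = base + rnorm(length(bins), 0, noise_sd))
    })
  })
}
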