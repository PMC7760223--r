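spec_tbl <- function(mz, intensity) tibble::tibble(mz = mz,
                                                   intensity = intensity)

test_that("binning keeps the 200-1200 u range and normalises to 100%", {
  one <- preprocess_spectrum(spec_tbl(500, 7))
  expect_equal(one$mass_u, 500L)
  expect_equal(one$intensity_pct, 100)
  # the low-mass metal-oxide region is excluded from the discriminant range
  two <- preprocess_spectrum(spec_tbl(c(156.12, 500.0), c(50, 7)))
  expect_equal(two$mass_u, 500L)
  expect_equal(two$intensity_pct, 100)
  eq <- preprocess_spectrum(spec_tbl(c(400.2, 700.4), c(3, 3)))
  expect_equal(eq$intensity_pct, c(50, 50))
})

test_that("binning rounds to nearest unit with .5 rounding up", {
  res <- preprocess_spectrum(spec_tbl(c(615.49, 615.5), c(1, 1)))
  expect_equal(res$mass_u, c(615L, 616L))
  # channels falling into the same unit bin are summed
  summed <- preprocess_spectrum(spec_tbl(c(700.1, 700.4), c(2, 3)))
  expect_equal(summed$mass_u, 700L)
  expect_equal(summed$intensity_pct, 100)
})

test_that("preprocessing is idempotent and errors on empty ranges", {
  once <- preprocess_spectrum(spec_tbl(c(300.3, 791.6), c(2, 5)))
  again <- preprocess_spectrum(
    spec_tbl(as.numeric(once$mass_u), once$intensity_pct))
  expect_equal(again, once, tolerance = 1e-12)
  expect_error(preprocess_spectrum(spec_tbl(150, 1)),
               class = "alidose_spectrum_error")
  expect_error(preprocess_spectrum(spec_tbl(c(500, 400), c(1, 1))),
               class = "alidose_input_error")
})

test_that("every simulated spectrum normalises to exactly 100%", {
  binned <- preprocess_spectra(
    simulate_tofsims_spectra(ali_sim_config(seed = 41)))
  sums <- binned |>
    dplyr::group_by(group, replicate_id) |>
    dplyr::summarise(s = sum(intensity_pct), .groups = "drop")
  expect_equal(sums$s, rep(100, nrow(sums)), tolerance = 1e-9)
})

test_that("PCA separates groups differing in one bin and finds its loading", {
  binned <- make_binned(shift = 10, noise_sd = 0)
  p <- pca_scores(binned)
  expect_true(all(tapply(p$scores$PC1, p$scores$group,
                         function(x) diff(range(x))) < 1e-9))
  g_means <- tapply(p$scores$PC1, p$scores$group, mean)
  expect_gt(abs(diff(g_means)), 1)
  expect_gt(abs(p$loadings["400", 1]), 0.999)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lte(sum(p$explained_variance), 1 + 1e-9)
})

test_that("duplicated spectra give identical scores and zero variance", {
  one <- tibble::tibble(group = "g", replicate_id = c("a", "b", "c"),
                        mass_u = 400L, intensity_pct = 100)
  p <- pca_scores(one)
  expect_equal(diff(range(p$scores$PC1)), 0)
  expect_equal(sum(p$explained_variance), 0)
  expect_error(pca_scores(one[1, ]), class = "alidose_input_error")
})

test_that("LOOCV is perfect on separable groups and bounded in [0, 1]", {
  binned <- preprocess_spectra(
    simulate_tofsims_spectra(ali_sim_config(seed = 42)))
  res <- fisher_lda_loocv(binned)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$n_folds, 12)
  expect_true(all(res$predictions$correct))
  disjoint <- make_binned(shift = 100, noise_sd = 0.5, seed = 2)
  expect_equal(fisher_lda_loocv(disjoint)$accuracy, 1.0)
})

test_that("LOOCV hovers near chance for identically distributed groups", {
  accs <- vapply(1:10, function(s) {
    fisher_lda_loocv(make_binned(shift = 0, noise_sd = 1, seed = 100 + s))$accuracy
  }, numeric(1))
  expect_true(all(accs >= 0 & accs <= 1))
  # central 99% band of Binomial(12, 1/2)/12 applied to the mean
  expect_gte(mean(accs), qbinom(0.005, 12, 0.5) / 12)
  expect_lte(mean(accs), qbinom(0.995, 12, 0.5) / 12)
})

test_that("the shrinkage discriminant matches MASS::lda on well-posed data", {
  binned <- make_binned(n = 6, shift = 15, noise_sd = 1.5, seed = 7)
  ours <- fisher_lda_loocv(binned, lambda = 0.01)
  wide <- tidyr::pivot_wider(binned, id_cols = c("group", "replicate_id"),
                             names_from = "mass_u",
                             values_from = "intensity_pct")
  x <- as.matrix(wide[, c("300", "400", "500")])
  ref <- MASS::lda(x, grouping = wide$group, CV = TRUE)
  expect_equal(ours$predictions$predicted, as.character(ref$class))
})

test_that("LDA input contracts are enforced", {
  one_group <- make_binned()
  one_group$group <- "same"
  expect_error(fisher_lda_loocv(one_group), class = "alidose_input_error")
  few <- make_binned(n = 1)
  expect_error(fisher_lda_loocv(few), class = "alidose_input_error")
})

test_that("ion-yield comparison reports relative intensity and significance", {
  mk <- function(vals, group) purrr::map_dfr(seq_along(vals), function(i)
    tibble::tibble(group = group, replicate_id = paste0(group, i),
                   mass_u = 791L, intensity_pct = vals[i]))
  same <- dplyr::bind_rows(mk(c(10, 10, 10), "control"),
                           mk(c(10, 10, 10), "exposed"))
  r <- compare_ion_yields(same, 791L, exposed = "exposed")
  expect_equal(r$relative_pct, 100)
  expect_false(r$significant)
  half <- dplyr::bind_rows(mk(c(10, 10, 10), "control"),
                           mk(c(5, 5, 5), "exposed"))
  r2 <- compare_ion_yields(half, 791L, exposed = "exposed")
  expect_equal(r2$relative_pct, 50)
  expect_true(r2$significant)
  zero <- dplyr::bind_rows(mk(c(0, 0, 0), "control"),
                           mk(c(5, 5, 5), "exposed"))
  r3 <- compare_ion_yields(zero, 791L, exposed = "exposed")
  expect_true(is.na(r3$relative_pct))
})

test_that("simulated exposure depresses the lipid target ions", {
  binned <- preprocess_spectra(
    simulate_tofsims_spectra(ali_sim_config(seed = 43)))
  res <- compare_ion_yields(binned, c(626L, 778L, 792L, 814L),
                            exposed = "exposed_4h")
  expect_true(all(res$relative_pct < 100))
})

test_that("two-column spectrum files round-trip through the reader", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# spectrum", "500.4 7", "791.6 3"), tmp)
  s <- read_tofsims_txt(tmp, group = "control", replicate_id = "r1")
  expect_equal(s$mz, c(500.4, 791.6))
  expect_equal(s$intensity, c(7, 3))
  b <- preprocess_spectrum(s)
  expect_equal(sum(b$intensity_pct), 100)
})
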