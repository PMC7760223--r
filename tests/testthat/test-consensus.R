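one_condition <- function(y_by_plate, condition = "c") {
  purrr::imap_dfr(y_by_plate, function(y, p)
    tibble::tibble(condition = condition, plate_id = p, viability_pct = y))
}

test_that("single-level reduction matches the conjugate Gaussian posterior", {
  set.seed(42)
  y <- rnorm(20, 85, 10)
  v <- one_condition(list(p1 = y))
  spec <- consensus_model_spec(n_iterations = 8000, seed = 3,
                               sigma_fixed = 10, tau_fixed = 0)
  fit <- fit_consensus(v, spec)
  # closed-form conjugate oracle
  prec <- length(y) / 100 + 1 / 1000^2
  post_mean <- (sum(y) / 100 + 100 / 1000^2) / prec
  post_sd <- sqrt(1 / prec)
  mu <- fit$fits$c$mu_draws
  mc_se <- post_sd / sqrt(length(mu) / 10) # generous autocorrelation margin
  expect_lt(abs(mean(mu) - post_mean), 4 * mc_se)
  expect_lt(abs(sd(mu) / post_sd - 1), 0.1)
  expect_equal(quantile(mu, 0.025, names = FALSE),
               post_mean - 1.96 * post_sd, tolerance = 0.05 * post_sd * 10)
})

test_that("identical observations shrink the consensus onto their value", {
  v <- one_condition(list(p1 = rep(85, 5), p2 = rep(85, 5), p3 = rep(85, 5)))
  fit <- fit_consensus(v, quick_spec(seed = 4, n_iterations = 3000))
  td <- tidy(fit, parameters = "consensus")
  expect_lt(abs(td$estimate - 85), 0.5)
  expect_lt(td$conf.high - td$conf.low, 5)
  expect_true(td$conf.low <= 85 && td$conf.high >= 85)
})

test_that("posterior summaries are identical under a fixed sampler seed", {
  v <- compute_viability(
    simulate_plate_readings(ali_sim_config(seed = 31)))
  f1 <- fit_consensus(v, quick_spec(seed = 9), conditions = "air_5ml_min")
  f2 <- fit_consensus(v, quick_spec(seed = 9), conditions = "air_5ml_min")
  expect_identical(tidy(f1), tidy(f2))
})

test_that("the consensus mean stays inside the hull of the plate means", {
  for (s in 1:5) {
    set.seed(s)
    y <- lapply(1:3, function(j) rnorm(4, runif(1, 40, 95), 8))
    names(y) <- paste0("p", 1:3)
    fit <- fit_consensus(one_condition(y), quick_spec(seed = s,
                                                      n_iterations = 1500))
    est <- tidy(fit, parameters = "consensus")$estimate
    means <- vapply(y, mean, numeric(1))
    expect_gt(est, min(means) - 0.5)
    expect_lt(est, max(means) + 0.5)
  }
})

test_that("significance calls flag low conditions and spare the control", {
  cfg <- ali_sim_config(seed = 33, condition_truths = c(low = 39, same = 100))
  v <- compute_viability(simulate_plate_readings(cfg))
  fit <- fit_consensus(v, quick_spec(seed = 13, n_iterations = 2000),
                       conditions = c("low", "same", "incubator_control"))
  sig <- significance_calls(fit)
  expect_true(sig$calls$flag_less_than_control[sig$calls$condition == "low"])
  expect_false(sig$calls$flag_less_than_control[sig$calls$condition == "same"])
  expect_true(all(sig$calls$prob_below_100 >= 0 & sig$calls$prob_below_100 <= 1))
  # identical-truth pair is called statistically equal, distant pair is not
  pw <- sig$pairwise
  eq_row <- pw[pw$condition_a == "same" & pw$condition_b == "incubator_control" |
                 pw$condition_b == "same" & pw$condition_a == "incubator_control", ]
  expect_true(eq_row$equal)
  lo_row <- pw[pw$condition_a == "low" & pw$condition_b == "incubator_control" |
                 pw$condition_b == "low" & pw$condition_a == "incubator_control", ]
  expect_false(lo_row$equal)
})

test_that("fallback consensus reproduces the homogeneous-plates case", {
  res <- fallback_consensus(c(80, 80, 80), c(2, 2, 2))
  expect_equal(res$consensus, 80)
  expect_equal(res$tau2, 0)
  expect_equal(res$se, 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(res$conf.high - res$consensus, qnorm(0.975) * 2 / sqrt(3),
               tolerance = 1e-12)
})

test_that("fallback consensus matches the hand DerSimonian-Laird result", {
  # w = 1 each; Q = 200; c = 1; tau2 = 199; weights 1/200 -> consensus 80
  res <- fallback_consensus(c(70, 90), c(1, 1))
  expect_equal(res$consensus, 80, tolerance = 1e-12)
  expect_equal(res$tau2, 199, tolerance = 1e-12)
  expect_equal(res$se, 10, tolerance = 1e-12)
})

test_that("fallback consensus agrees with metafor's DL estimator", {
  set.seed(5)
  yi <- c(72.3, 88.1, 80.4, 91.0)
  sei <- c(2.1, 3.4, 1.7, 4.2)
  res <- fallback_consensus(yi, sei)
  rma <- metafor::rma(yi = yi, sei = sei, method = "DL")
  expect_equal(res$consensus, as.numeric(rma$beta), tolerance = 1e-8)
  expect_equal(res$tau2, rma$tau2, tolerance = 1e-8)
  expect_equal(res$se, rma$se, tolerance = 1e-8)
})

test_that("all-zero uncertainties fall back to the unweighted limit", {
  res <- fallback_consensus(c(70, 80, 90), c(0, 0, 0))
  expect_equal(res$consensus, 80)
  expect_equal(res$tau2, var(c(70, 80, 90)))
})

test_that("a single plate returns its own mean with a warning", {
  expect_warning(res <- fallback_consensus(80, 2), "Single plate")
  expect_equal(res$consensus, 80)
  expect_equal(res$conf.high, 80 + qnorm(0.975) * 2)
})

test_that("split-R-hat distinguishes mixed from disjoint chains", {
  set.seed(6)
  iid <- matrix(rnorm(4000), ncol = 4)
  d <- convergence_check(iid)
  expect_gt(d$rhat, 0.999) # >= 1 up to numerical tolerance
  expect_lt(d$rhat, 1.05)
  expect_gt(d$ess, 1000)
  disjoint <- cbind(rep(0, 100), rep(10, 100))
  expect_gt(convergence_check(disjoint)$rhat, 1.05)
  dup <- matrix(rep(rnorm(500), 2), ncol = 2)
  expect_lt(convergence_check(dup)$rhat, 1.01)
  expect_error(convergence_check(matrix(rnorm(100), ncol = 1)),
               class = "alidose_input_error")
})

test_that("hierarchical fit and fallback combiner agree on well-behaved data", {
  overlap <- logical(10)
  for (i in 1:10) {
    cfg <- ali_sim_config(seed = 400 + i, condition_truths = c(t = 85))
    v <- compute_viability(simulate_plate_readings(cfg))
    vt <- v[v$condition == "t", ]
    fit <- fit_consensus(vt, quick_spec(seed = i, n_iterations = 1500))
    td <- tidy(fit, parameters = "consensus")
    pm <- tapply(vt$viability_pct, vt$plate_id, mean)
    pu <- tapply(vt$viability_pct, vt$plate_id,
                 function(x) sd(x) / sqrt(length(x)))
    fb <- fallback_consensus(as.numeric(pm), as.numeric(pu))
    overlap[i] <- td$conf.low <= fb$conf.high && fb$conf.low <= td$conf.high
  }
  expect_true(all(overlap))
})
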