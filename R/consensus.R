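# Hierarchical Bayesian consensus of percentage viability across plates.
#
# Model, per condition:
#   y_ij | theta_j, sigma_j ~ Normal(theta_j, sigma_j^2)   (insert i, plate j)
#   theta_j | mu, tau       ~ Normal(mu, tau^2)
#   mu                      ~ Normal(prior_mean_center, prior_mean_sd^2)
#   sigma_j ~ Half-Cauchy(scale_within),  tau ~ Half-Cauchy(scale_between)
#
# Sampling uses the inverse-gamma auxiliary-variable representation of the
# Half-Cauchy prior (sigma^2 | a ~ IG(1/2, 1/a), a ~ IG(1/2, 1/A^2) implies
# sigma ~ Half-Cauchy(A)), which makes every full conditional conjugate and
# the whole sampler a plain Gibbs scheme: fast, tuning-free and exact in the
# same sense as any MCMC.

#' Specification of the hierarchical consensus model
#'
#' @param prior_mean_center,prior_mean_sd Gaussian prior on the consensus mean
#'   `mu`, in % viability units. The default (100, 1000) is effectively flat
#'   over the assay's range and centred at the control.
#' @param halfcauchy_scale_within,halfcauchy_scale_between Scales of the
#'   Half-Cauchy priors on the within-plate sds `sigma_j` and the
#'   between-plate sd `tau` (% viability units). 25 is weakly informative for
#'   plate assays whose values live on a 0-100 scale.
#' @param n_chains Number of independent chains (>= 2 for diagnostics).
#' @param n_iterations Iterations per chain, including burn-in.
#' @param burn_in_fraction Fraction of each chain discarded as burn-in.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed for the sampler.
#' @param rhat_threshold Split-R-hat above which a fit is declared
#'   non-converged (1.05, stricter than the common 1.1, so the fallback
#'   combiner is triggered conservatively).
#' @param sigma_fixed,tau_fixed Optional fixed values for the within-plate sd
#'   (one value, recycled) and the between-plate sd; used for reductions of
#'   the model (e.g. a single-level Gaussian with known variance) and in
#'   validation against conjugate closed forms. `NULL` (default) samples them.
#' @return An object of class `ali_model_spec`.
#' @export
consensus_model_spec <- function(prior_mean_center = 100, prior_mean_sd = 1000,
                                 halfcauchy_scale_within = 25,
                                 halfcauchy_scale_between = 25,
                                 n_chains = 4L, n_iterations = 4000L,
                                 burn_in_fraction = 0.5, thin = 1L, seed = 1L,
                                 rhat_threshold = 1.05,
                                 sigma_fixed = NULL, tau_fixed = NULL) {
  if (halfcauchy_scale_within <= 0 || halfcauchy_scale_between <= 0 ||
      prior_mean_sd <= 0)
    abort("Prior scales must be > 0.", class = "alidose_config_error")
  if (n_chains < 2L)
    abort("At least 2 chains are required for convergence diagnostics.",
          class = "alidose_config_error")
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    abort("`burn_in_fraction` must be in [0, 1).", class = "alidose_config_error")
  structure(list(prior_mean_center = prior_mean_center,
                 prior_mean_sd = prior_mean_sd,
                 halfcauchy_scale_within = halfcauchy_scale_within,
                 halfcauchy_scale_between = halfcauchy_scale_between,
                 n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 burn_in_fraction = burn_in_fraction, thin = as.integer(thin),
                 seed = as.integer(seed), rhat_threshold = rhat_threshold,
                 sigma_fixed = sigma_fixed, tau_fixed = tau_fixed),
            class = "ali_model_spec")
}

rinvgamma1 <- function(shape, rate) 1 / rgamma(length(rate), shape = shape, rate = rate)

# One chain of the Gibbs sampler for one condition. y: list of numeric vectors
# (one per plate). Returns a matrix of kept draws with named columns.
gibbs_chain <- function(y, spec, chain_seed) {
  set.seed(chain_seed)
  J <- length(y)
  n_j <- lengths(y)
  ybar <- vapply(y, mean, numeric(1))
  Aw2 <- spec$halfcauchy_scale_within^2
  Ab2 <- spec$halfcauchy_scale_between^2
  m0 <- spec$prior_mean_center
  s02 <- spec$prior_mean_sd^2
  fix_sigma <- !is.null(spec$sigma_fixed)
  fix_tau <- !is.null(spec$tau_fixed)
  tau_zero <- fix_tau && spec$tau_fixed == 0

  theta <- ybar
  mu <- mean(ybar)
  sigma2 <- if (fix_sigma) rep(spec$sigma_fixed^2, J) else
    pmax(vapply(y, function(v) if (length(v) > 1) var(v) else 1, numeric(1)), 1e-6)
  tau2 <- if (fix_tau) spec$tau_fixed^2 else max(var(theta), 1e-6)
  a_sig <- rep(1, J)
  a_tau <- 1

  n_iter <- spec$n_iterations
  burn <- floor(spec$burn_in_fraction * n_iter)
  keep_idx <- seq(burn + 1L, n_iter, by = spec$thin)
  out <- matrix(NA_real_, length(keep_idx), J + 2L)
  colnames(out) <- c("mu", paste0("theta_", seq_len(J)), "tau")
  k <- 0L

  for (it in seq_len(n_iter)) {
    if (tau_zero) {
      # single-level reduction: theta_j == mu, pooled conjugate update
      prec <- sum(n_j / sigma2) + 1 / s02
      mean_mu <- (sum(n_j * ybar / sigma2) + m0 / s02) / prec
      mu <- rnorm(1, mean_mu, sqrt(1 / prec))
      theta <- rep(mu, J)
    } else {
      prec_t <- n_j / sigma2 + 1 / tau2
      mean_t <- (n_j * ybar / sigma2 + mu / tau2) / prec_t
      theta <- rnorm(J, mean_t, sqrt(1 / prec_t))
      prec_m <- J / tau2 + 1 / s02
      mu <- rnorm(1, (sum(theta) / tau2 + m0 / s02) / prec_m, sqrt(1 / prec_m))
    }
    if (!fix_sigma) {
      ss <- vapply(seq_len(J), function(j) sum((y[[j]] - theta[j])^2), numeric(1))
      sigma2 <- rinvgamma1((n_j + 1) / 2, 1 / a_sig + ss / 2)
      a_sig <- rinvgamma1(1, 1 / Aw2 + 1 / sigma2)
    }
    if (!fix_tau) {
      sst <- sum((theta - mu)^2)
      tau2 <- rinvgamma1((J + 1) / 2, 1 / a_tau + sst / 2)
      a_tau <- rinvgamma1(1, 1 / Ab2 + 1 / tau2)
    }
    if (it > burn && ((it - burn - 1L) %% spec$thin == 0L)) {
      k <- k + 1L
      out[k, ] <- c(mu, theta, sqrt(tau2))
    }
  }
  out
}

#' Fit the hierarchical consensus model to viability records
#'
#' Per condition, insert viabilities are Gaussian within each plate, plate
#' means are Gaussian around a consensus mean `mu`, and all sds carry
#' Half-Cauchy priors (see [consensus_model_spec()]). Multiple seeded chains
#' are run by conjugate Gibbs sampling; split-R-hat and effective sample size
#' are computed per parameter, and a fit whose worst R-hat exceeds the
#' threshold is flagged non-converged, directing the caller to
#' [fallback_consensus()] on per-plate summaries.
#'
#' @param viability Tibble of viability records with columns `condition`,
#'   `plate_id`, `viability_pct` (e.g. from [compute_viability()]).
#' @param spec A [consensus_model_spec()].
#' @param conditions Conditions to fit (default: all in the data).
#' @return An object of class `ali_consensus` with `tidy()`, `glance()` and
#'   `autoplot()` methods. Per condition it stores posterior draws of the
#'   consensus mean and plate means, posterior means, central 95% credible
#'   intervals, R-hat and ESS.
#' @export
#' @examples
#' v <- compute_viability(simulate_plate_readings(ali_sim_config(seed = 2)))
#' fit <- fit_consensus(v, consensus_model_spec(n_iterations = 500, seed = 2),
#'                      conditions = "air_5ml_min")
#' tidy(fit)
fit_consensus <- function(viability, spec = consensus_model_spec(),
                          conditions = NULL) {
  stopifnot(inherits(spec, "ali_model_spec"))
  required <- c("condition", "plate_id", "viability_pct")
  if (!all(required %in% names(viability)))
    abort("`viability` needs columns condition, plate_id, viability_pct.",
          class = "alidose_input_error")
  if (is.null(conditions)) conditions <- unique(viability$condition)
  fits <- lapply(setNames(conditions, conditions), function(cond) {
    df <- viability[viability$condition == cond, ]
    if (!nrow(df))
      abort(sprintf("No records for condition '%s'.", cond),
            class = "alidose_input_error")
    y <- split(df$viability_pct, df$plate_id)
    plates <- names(y)
    chains <- lapply(seq_len(spec$n_chains), function(c)
      gibbs_chain(y, spec, chain_seed = spec$seed + 1000L * c +
                    match(cond, conditions)))
    draws <- array(unlist(chains),
                   dim = c(nrow(chains[[1]]), ncol(chains[[1]]), spec$n_chains),
                   dimnames = list(NULL, colnames(chains[[1]]), NULL))
    diag <- convergence_check(draws)
    all_d <- apply(draws, 2, identity)  # pooled draws, iterations*chains x par
    summ <- tibble::tibble(
      parameter = colnames(all_d),
      estimate = colMeans(all_d),
      conf.low = apply(all_d, 2, quantile, 0.025, names = FALSE),
      conf.high = apply(all_d, 2, quantile, 0.975, names = FALSE)) |>
      dplyr::left_join(diag, by = "parameter")
    list(condition = cond, plates = plates, draws = draws, summary = summ,
         mu_draws = as.vector(draws[, "mu", ]),
         converged = all(diag$rhat < spec$rhat_threshold, na.rm = TRUE))
  })
  structure(list(fits = fits, spec = spec), class = "ali_consensus")
}

#' @export
print.ali_consensus <- function(x, ...) {
  cat("<ali_consensus>", length(x$fits), "condition(s)\n")
  print(tidy(x, parameters = "consensus"), ...)
  invisible(x)
}

#' @rdname fit_consensus
#' @param x,object An `ali_consensus` fit.
#' @param parameters `"all"`, `"consensus"` (the `mu` rows only) or
#'   `"plates"`.
#' @param ... Unused.
#' @export
tidy.ali_consensus <- function(x, parameters = "all", ...) {
  out <- purrr::map_dfr(x$fits, function(f) {
    s <- f$summary
    s$condition <- f$condition
    is_theta <- grepl("^theta_", s$parameter)
    s$term <- s$parameter
    s$term[s$parameter == "mu"] <- "consensus"
    s$term[is_theta] <- paste0(
      "plate:", f$plates[as.integer(sub("theta_", "", s$parameter[is_theta]))])
    s$converged <- f$converged
    s[, c("condition", "term", "estimate", "conf.low", "conf.high",
          "rhat", "ess", "converged")]
  })
  switch(parameters,
         all = out,
         consensus = out[out$term == "consensus", ],
         plates = out[startsWith(out$term, "plate:"), ])
}

#' @rdname fit_consensus
#' @export
glance.ali_consensus <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(n_conditions = length(x$fits),
                 max_rhat = max(td$rhat, na.rm = TRUE),
                 min_ess = min(td$ess, na.rm = TRUE),
                 converged = all(vapply(x$fits, `[[`, logical(1), "converged")))
}

#' Posterior significance calls against the control
#'
#' A condition is flagged as below the control when more than 95% of the
#' posterior draws of its consensus mean fall below the reference (100%),
#' i.e. the consensus value is less than the control with at least 95%
#' likelihood. Two conditions are called statistically equal when the central
#' 95% credible interval of the difference of their consensus means contains
#' zero.
#'
#' @param fit An [fit_consensus()] result.
#' @param reference Reference viability (% of control; default 100).
#' @param prob Posterior probability required to flag (default 0.95).
#' @return List of class `ali_significance` with `calls` (tibble: `condition`,
#'   `prob_below_100`, `flag_less_than_control`) and `pairwise` (tibble:
#'   `condition_a`, `condition_b`, `diff_low`, `diff_high`, `equal`).
#' @export
significance_calls <- function(fit, reference = 100, prob = 0.95) {
  stopifnot(inherits(fit, "ali_consensus"))
  calls <- purrr::map_dfr(fit$fits, function(f) {
    p <- mean(f$mu_draws < reference)
    tibble::tibble(condition = f$condition, prob_below_100 = p,
                   flag_less_than_control = p > prob)
  })
  conds <- names(fit$fits)
  pairwise <- NULL
  if (length(conds) > 1) {
    pairs <- utils::combn(conds, 2)
    pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      a <- fit$fits[[pairs[1, i]]]$mu_draws
      b <- fit$fits[[pairs[2, i]]]$mu_draws
      n <- min(length(a), length(b))
      d <- a[seq_len(n)] - b[seq_len(n)]
      ci <- quantile(d, c(0.025, 0.975), names = FALSE)
      tibble::tibble(condition_a = pairs[1, i], condition_b = pairs[2, i],
                     diff_low = ci[1], diff_high = ci[2],
                     equal = ci[1] <= 0 && ci[2] >= 0)
    })
  }
  structure(list(calls = calls, pairwise = pairwise),
            class = "ali_significance")
}

#' @export
print.ali_significance <- function(x, ...) {
  print(x$calls, ...)
  if (!is.null(x$pairwise)) print(x$pairwise, ...)
  invisible(x)
}

#' Random-effects consensus from per-plate summaries
#'
#' Non-MCMC combiner used when the hierarchical fit does not converge:
#' between-plate variance by the DerSimonian-Laird moment estimator (floored
#' at zero), consensus as the inverse-variance weighted mean with weights
#' `1 / (u_j^2 + tau^2)`, and 95% bounds from the normal quantile on the
#' combined standard uncertainty. When every standard uncertainty is zero the
#' estimator's limit is used: equal weights and `tau^2` equal to the sample
#' variance of the plate means.
#'
#' @param plate_means Per-plate mean viabilities (%).
#' @param plate_uncertainties Per-plate standard uncertainties (%), same
#'   length.
#' @param conf_level Confidence level for the bounds (default 0.95).
#' @return One-row tibble: `consensus`, `se`, `conf.low`, `conf.high`, `tau2`,
#'   `n_plates`.
#' @export
#' @examples
#' fallback_consensus(c(70, 90), c(1, 1)) # consensus 80, tau2 > 0
fallback_consensus <- function(plate_means, plate_uncertainties,
                               conf_level = 0.95) {
  if (length(plate_means) != length(plate_uncertainties))
    abort("Means and uncertainties must have the same length.",
          class = "alidose_input_error")
  if (any(plate_uncertainties < 0))
    abort("Standard uncertainties must be >= 0.", class = "alidose_input_error")
  k <- length(plate_means)
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (k == 1L) {
    warn("Single plate: returning its mean and bounds, no consensus possible.")
    se <- plate_uncertainties
    return(tibble::tibble(consensus = plate_means, se = se,
                          conf.low = plate_means - z * se,
                          conf.high = plate_means + z * se,
                          tau2 = NA_real_, n_plates = 1L))
  }
  u2 <- plate_uncertainties^2
  if (all(u2 == 0)) {
    tau2 <- var(plate_means)
    wstar <- rep(1 / max(tau2, .Machine$double.eps), k)
  } else {
    if (any(u2 == 0))
      abort("Mixed zero and non-zero uncertainties are not combinable.",
            class = "alidose_input_error")
    w <- 1 / u2
    yw <- sum(w * plate_means) / sum(w)
    Q <- sum(w * (plate_means - yw)^2)
    cc <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - (k - 1)) / cc)
    wstar <- 1 / (u2 + tau2)
  }
  consensus <- sum(wstar * plate_means) / sum(wstar)
  se <- sqrt(1 / sum(wstar))
  tibble::tibble(consensus = consensus, se = se,
                 conf.low = consensus - z * se, conf.high = consensus + z * se,
                 tau2 = tau2, n_plates = k)
}

#' Split-R-hat and effective sample size
#'
#' Gelman-Rubin potential scale reduction computed after splitting each chain
#' in half (so within-chain drift also inflates R-hat), plus an effective
#' sample size from chain-averaged autocorrelations truncated by Geyer's
#' initial positive-sequence rule.
#'
#' @param chains Either a matrix (iterations x chains) for one parameter or a
#'   3-d array (iterations x parameters x chains) with named parameter
#'   dimension.
#' @return Tibble with `parameter`, `rhat`, `ess`.
#' @export
convergence_check <- function(chains) {
  if (is.matrix(chains))
    chains <- array(chains, dim = c(nrow(chains), 1L, ncol(chains)),
                    dimnames = list(NULL, "parameter", NULL))
  if (length(dim(chains)) != 3L)
    abort("`chains` must be a matrix or a 3-d array.",
          class = "alidose_input_error")
  if (dim(chains)[3] < 2L)
    abort("At least 2 chains are required.", class = "alidose_input_error")
  pars <- dimnames(chains)[[2]]
  purrr::map_dfr(seq_along(pars), function(p) {
    m <- chains[, p, ]
    tibble::tibble(parameter = pars[p],
                   rhat = split_rhat(m), ess = ess_acf(m))
  })
}

split_rhat <- function(m) {
  n <- nrow(m)
  half <- floor(n / 2)
  sub <- cbind(m[seq_len(half), , drop = FALSE],
               m[seq(n - half + 1L, n), , drop = FALSE])
  W <- mean(apply(sub, 2, var))
  B <- half * var(colMeans(sub))
  if (!is.finite(W) || W == 0) return(if (B == 0 || !is.finite(B)) 1 else Inf)
  sqrt(((half - 1) / half * W + B / half) / W)
}

ess_acf <- function(m) {
  n <- nrow(m); nc <- ncol(m)
  if (all(apply(m, 2, var) == 0)) return(NA_real_)
  max_lag <- min(n - 1L, 200L)
  rho <- rowMeans(vapply(seq_len(nc), function(c) {
    v <- m[, c]
    if (var(v) == 0) rep(0, max_lag + 1L)
    else as.vector(acf(v, lag.max = max_lag, plot = FALSE,
                       demean = TRUE)$acf)
  }, numeric(max_lag + 1L)))
  # Geyer initial positive sequence on paired sums
  s <- 0
  t <- 1L
  while (t + 1L <= max_lag) {
    pair <- rho[t + 1L] + rho[t + 2L]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
    t <- t + 2L
  }
  max(1, (n * nc) / (1 + 2 * s))
}
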