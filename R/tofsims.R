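# ToF-SIMS spectral statistics: unit-mass binning with a mass-range
# restriction and peak-sum normalisation, PCA, a shrinkage Fisher
# discriminant with leave-one-out cross-validation, and per-ion group
# comparison.

#' Bin, filter and normalise one spectrum
#'
#' Channel intensities are summed into nearest-integer mass-unit bins (ties
#' at .5 round up), bins outside `[range_low, range_high]` are dropped (the
#' low-mass region is dominated by salts and system contaminants), and the
#' retained bins are rescaled so their sum is 100%. Idempotent on
#' already-binned, already-normalised input.
#'
#' @param spectrum Tibble with `mz` (strictly increasing) and `intensity`
#'   (finite, >= 0) for one spectrum; extra columns are ignored.
#' @param range_low,range_high Retained mass range in u (defaults 200-1200).
#' @return Tibble with `mass_u` (integer) and `intensity_pct` summing to 100.
#' @export
#' @examples
#' preprocess_spectrum(tibble::tibble(mz = c(500.4, 791.6),
#'                                    intensity = c(1, 3)))
preprocess_spectrum <- function(spectrum, range_low = 200, range_high = 1200) {
  if (!all(c("mz", "intensity") %in% names(spectrum)))
    abort("A spectrum needs columns mz and intensity.",
          class = "alidose_input_error")
  if (is.unsorted(spectrum$mz, strictly = TRUE))
    abort("m/z values must be strictly increasing.",
          class = "alidose_input_error")
  if (any(!is.finite(spectrum$intensity)) || any(spectrum$intensity < 0))
    abort("Intensities must be finite and >= 0.", class = "alidose_input_error")
  binned <- spectrum |>
    dplyr::mutate(mass_u = as.integer(floor(.data$mz + 0.5))) |>
    dplyr::filter(.data$mass_u >= range_low, .data$mass_u <= range_high) |>
    dplyr::group_by(.data$mass_u) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")
  total <- sum(binned$intensity)
  if (!nrow(binned) || total <= 0)
    abort("No signal inside the retained mass range.",
          class = "alidose_spectrum_error")
  tibble::tibble(mass_u = binned$mass_u,
                 intensity_pct = 100 * binned$intensity / total)
}

#' Bin, filter and normalise a collection of spectra
#'
#' Applies [preprocess_spectrum()] per (`group`, `replicate_id`) and returns
#' the long binned table the multivariate functions consume.
#'
#' @param spectra Long tibble with `group`, `replicate_id`, `mz`,
#'   `intensity`.
#' @inheritParams preprocess_spectrum
#' @return Long tibble: `group`, `replicate_id`, `mass_u`, `intensity_pct`.
#' @export
preprocess_spectra <- function(spectra, range_low = 200, range_high = 1200) {
  spectra |>
    dplyr::group_by(.data$group, .data$replicate_id) |>
    dplyr::group_modify(function(df, key)
      preprocess_spectrum(dplyr::arrange(df, .data$mz),
                          range_low = range_low, range_high = range_high)) |>
    dplyr::ungroup()
}

# Long binned table -> spectra x bins matrix (missing bins are true zeros).
binned_matrix <- function(binned) {
  wide <- binned |>
    tidyr::pivot_wider(id_cols = c("group", "replicate_id"),
                       names_from = "mass_u", values_from = "intensity_pct",
                       values_fill = 0)
  m <- as.matrix(wide[, setdiff(names(wide), c("group", "replicate_id"))])
  storage.mode(m) <- "double"
  list(x = m, group = wide$group, replicate_id = wide$replicate_id)
}

#' PCA scores of binned spectra
#'
#' Centred (unscaled) principal component analysis over all retained bins.
#'
#' @param binned Long binned table from [preprocess_spectra()].
#' @return Object of class `ali_pca`: `scores` (tibble with `group`,
#'   `replicate_id`, `PC1`, `PC2`, ...) and `explained_variance` (fractions,
#'   non-increasing, summing to <= 1).
#' @export
pca_scores <- function(binned) {
  bm <- binned_matrix(binned)
  if (nrow(bm$x) < 2L)
    abort("At least 2 spectra are required for PCA.",
          class = "alidose_input_error")
  p <- prcomp(bm$x, center = TRUE, scale. = FALSE)
  total_var <- sum(p$sdev^2)
  ev <- if (total_var > 0) p$sdev^2 / total_var else rep(0, length(p$sdev))
  scores <- tibble::as_tibble(p$x)
  scores <- dplyr::bind_cols(tibble::tibble(group = bm$group,
                                            replicate_id = bm$replicate_id),
                             scores)
  structure(list(scores = scores, explained_variance = ev,
                 loadings = p$rotation), class = "ali_pca")
}

#' @export
print.ali_pca <- function(x, ...) {
  cat("<ali_pca>", nrow(x$scores), "spectra,",
      length(x$explained_variance), "components\n")
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained_variance, 4)),
            collapse = ", "), "...\n")
  invisible(x)
}

# Fisher discriminant with diagonal shrinkage of the within-group scatter.
# With many more bins than spectra the raw scatter is singular, so
# W_reg = (1 - lambda) W + lambda diag(W) + eps * mean(diag(W)) I.
fisher_fit <- function(x, group, lambda, eps = 1e-6) {
  groups <- unique(group)
  centroids <- t(vapply(groups, function(g)
    colMeans(x[group == g, , drop = FALSE]), numeric(ncol(x))))
  rownames(centroids) <- groups
  W <- matrix(0, ncol(x), ncol(x))
  for (g in groups) {
    xg <- x[group == g, , drop = FALSE]
    if (nrow(xg) > 1L) {
      d <- sweep(xg, 2, colMeans(xg))
      W <- W + crossprod(d)
    }
  }
  grand <- colMeans(x)
  B <- matrix(0, ncol(x), ncol(x))
  for (g in groups) {
    ng <- sum(group == g)
    v <- centroids[g, ] - grand
    B <- B + ng * tcrossprod(v)
  }
  Wr <- (1 - lambda) * W + lambda * diag(diag(W), ncol(x))
  diag(Wr) <- diag(Wr) + eps * mean(diag(W) + .Machine$double.eps)
  e <- eigen(solve(Wr, B))
  ncomp <- min(length(groups) - 1L, ncol(x))
  vecs <- Re(e$vectors[, seq_len(ncomp), drop = FALSE])
  list(projection = vecs,
       centroids = centroids %*% vecs,
       groups = groups)
}

fisher_predict <- function(fit, x) {
  z <- x %*% fit$projection
  pred <- apply(z, 1, function(row) {
    d2 <- rowSums(sweep(fit$centroids, 2, row)^2)
    rownames(fit$centroids)[which.min(d2)]
  })
  unname(pred)
}

#' Fisher discriminant with leave-one-out cross-validation
#'
#' Fits a Fisher linear discriminant on all spectra but one, classifies the
#' held-out spectrum by nearest group centroid in the discriminant space, and
#' repeats for every spectrum. Because the number of bins far exceeds the
#' number of spectra, the within-group scatter is shrunk toward its diagonal
#' (fixed `lambda`) plus a tiny ridge before inversion.
#'
#' @param binned Long binned table from [preprocess_spectra()] with >= 2
#'   groups and >= 2 spectra per group.
#' @param lambda Diagonal shrinkage weight in (0, 1]; default 0.1.
#' @return Object of class `ali_lda`: `accuracy` (fraction of held-out
#'   spectra classified correctly), `predictions` (tibble with `group`,
#'   `replicate_id`, `predicted`, `correct`) and `model` (the full-data fit).
#' @export
fisher_lda_loocv <- function(binned, lambda = 0.1) {
  bm <- binned_matrix(binned)
  tab <- table(bm$group)
  if (length(tab) < 2L)
    abort("At least 2 groups are required.", class = "alidose_input_error")
  if (any(tab < 2L))
    abort("At least 2 spectra per group are required.",
          class = "alidose_input_error")
  if (lambda <= 0 || lambda > 1)
    abort("`lambda` must be in (0, 1].", class = "alidose_input_error")
  n <- nrow(bm$x)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- fisher_fit(bm$x[-i, , drop = FALSE], bm$group[-i], lambda)
    pred[i] <- fisher_predict(fit, bm$x[i, , drop = FALSE])
  }
  predictions <- tibble::tibble(group = bm$group,
                                replicate_id = bm$replicate_id,
                                predicted = pred,
                                correct = pred == bm$group)
  structure(list(accuracy = mean(predictions$correct),
                 predictions = predictions,
                 model = fisher_fit(bm$x, bm$group, lambda),
                 n_folds = n),
            class = "ali_lda")
}

#' @export
print.ali_lda <- function(x, ...) {
  cat("<ali_lda> leave-one-out accuracy:",
      sprintf("%.3f (%d folds)\n", x$accuracy, x$n_folds))
  invisible(x)
}

#' Per-ion intensity relative to the control group
#'
#' For each target mass bin, the exposed group's mean normalised intensity as
#' a percentage of the control group's mean (control = 100%), with a
#' two-sample Welch test per bin and a significance flag at `alpha`. No
#' multiple-testing correction is applied by default, mirroring per-ion
#' reporting conventions; set `p_adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param binned Long binned table from [preprocess_spectra()].
#' @param targets Integer mass bins (u) to compare.
#' @param exposed,control Group labels.
#' @param alpha Significance level (default 0.05).
#' @param p_adjust Multiple-testing correction passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return Tibble: `mass_u`, `relative_pct`, `p_value`, `significant`,
#'   `n_exposed`, `n_control`. Bins whose control mean is zero are reported
#'   with missing values.
#' @export
compare_ion_yields <- function(binned, targets, exposed,
                               control = "control", alpha = 0.05,
                               p_adjust = "none") {
  for (lbl in c(exposed, control)) {
    if (!lbl %in% binned$group)
      abort(sprintf("Group '%s' not found.", lbl),
            class = "alidose_input_error")
  }
  get_vals <- function(grp, bin) {
    reps <- unique(binned$replicate_id[binned$group == grp])
    vapply(reps, function(r) {
      v <- binned$intensity_pct[binned$group == grp &
                                  binned$replicate_id == r &
                                  binned$mass_u == bin]
      if (length(v)) sum(v) else 0
    }, numeric(1))
  }
  out <- purrr::map_dfr(targets, function(bin) {
    ve <- get_vals(exposed, bin)
    vc <- get_vals(control, bin)
    if (length(ve) < 2L || length(vc) < 2L)
      abort("At least 2 spectra per group are required.",
            class = "alidose_input_error")
    if (mean(vc) == 0)
      return(tibble::tibble(mass_u = bin, relative_pct = NA_real_,
                            p_value = NA_real_, significant = NA,
                            n_exposed = length(ve), n_control = length(vc)))
    p <- if (var(ve) == 0 && var(vc) == 0) {
      if (mean(ve) == mean(vc)) 1 else 0
    } else t.test(ve, vc)$p.value
    tibble::tibble(mass_u = bin, relative_pct = 100 * mean(ve) / mean(vc),
                   p_value = p, significant = NA,
                   n_exposed = length(ve), n_control = length(vc))
  })
  out$p_value <- p.adjust(out$p_value, method = p_adjust)
  out$significant <- !is.na(out$p_value) & out$p_value <= alpha
  out
}
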