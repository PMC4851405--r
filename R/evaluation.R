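# Model evaluation: site-count sensitivity, site-holdout cross-validation
# (RMSE, r-squared, VIF), and correlation analyses over per-site summaries.

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` regresses column j on the other
#' columns (with intercept). Perfect collinearity yields `Inf` with a
#' warning.
#'
#' @param X Regressor matrix with at least 2 columns and more rows than
#'   columns.
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2L) stop("VIF needs at least 2 regressors", call. = FALSE)
  if (nrow(X) <= p) stop("need more rows than regressors", call. = FALSE)
  r2j <- vapply(seq_len(p), function(j) {
    r_squared(X[, -j, drop = FALSE], X[, j])
  }, numeric(1))
  out <- ifelse(r2j >= 1 - 1e-12, Inf, 1 / (1 - r2j))
  if (any(is.infinite(out))) {
    warning("perfect collinearity: VIF is infinite", call. = FALSE)
  }
  names(out) <- colnames(X)
  out
}

#' Sensitivity of model error to the number of pooled sites
#'
#' For each k in 1..n_sites, repeatedly draws k sites at random, refits the
#' fixed model specification's coefficients on them, and records the pooled
#' in-sample RMSE; reports the per-k mean and sd.
#'
#' @param sites List of `aligned_series` (>= 2).
#' @param model A `candidate_model` (its term structure is kept fixed).
#' @param reps Repetitions per model size (default 1000).
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `k`, `rmse_mean`, `rmse_sd`, `n_ok`.
#' @export
site_sensitivity <- function(sites, model, reps = 1000L, seed = NULL) {
  n <- length(sites)
  stopifnot(n >= 2L)
  if (!is.null(seed)) set.seed(seed)
  terms <- if (inherits(model, "candidate_model")) model$terms else model
  res <- lapply(seq_len(n), function(k) {
    rmses <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      idx <- sample.int(n, k)
      f <- tryCatch(refit_model(sites[idx], terms), error = function(e) NULL)
      if (!is.null(f)) rmses[r] <- sqrt(f$rss / f$n_obs)
    }
    ok <- !is.na(rmses)
    data.frame(k = k, rmse_mean = mean(rmses[ok]),
               rmse_sd = stats::sd(rmses[ok]), n_ok = sum(ok))
  })
  do.call(rbind, res)
}

#' Site-holdout cross-validation of a fixed model specification
#'
#' Per repetition, `n_test` sites are held out; the model's coefficients
#' are refitted on the remaining (training) sites and evaluated on the
#' pooled holdout rows: RMSE, r-squared, and the mean VIF of the holdout
#' design's regressors (single-regressor models get `NA` VIF).
#'
#' @param sites List of `aligned_series` (more than `n_test`).
#' @param model A `candidate_model` or list of [term_spec()]s.
#' @param n_test Number of holdout sites per repetition (default 3).
#' @param reps Repetitions (default 1000).
#' @param seed Optional integer seed.
#' @param r2_method `"pearson"` (default; squared Pearson correlation of
#'   predicted vs observed, as the headline summary) or `"rss"`
#'   (1 - SSE/SST on the holdout pool).
#' @return An `eval_summary`: list with `rmse_mean/sd`, `r2_mean/sd`,
#'   `vif_mean/sd`, `n_reps` (effective), `reps` (per-repetition data
#'   frame) and `per_site` (per-site mean holdout RMSE).
#' @export
holdout_cv <- function(sites, model, n_test = 3L, reps = 1000L, seed = NULL,
                       r2_method = c("pearson", "rss")) {
  n <- length(sites)
  stopifnot(n > n_test, n_test >= 1L)
  r2_method <- match.arg(r2_method)
  if (!is.null(seed)) set.seed(seed)
  terms <- if (inherits(model, "candidate_model")) model$terms else model
  ids <- vapply(sites, function(s) attr(s, "site_id"), character(1))

  rec <- data.frame(rmse = rep(NA_real_, reps), r2 = NA_real_, vif = NA_real_)
  site_rmse_sum <- stats::setNames(numeric(n), ids)
  site_rmse_n <- stats::setNames(integer(n), ids)
  n_discard <- 0L
  for (r in seq_len(reps)) {
    test_idx <- sample.int(n, n_test)
    fit <- tryCatch(refit_model(sites[-test_idx], terms),
                    error = function(e) NULL)
    if (is.null(fit)) { n_discard <- n_discard + 1L; next }
    d <- build_design(sites[test_idx], terms)
    if (nrow(d$X) <= ncol(d$X) + 1L) {
      message("holdout repetition discarded: evaluation design too short")
      n_discard <- n_discard + 1L
      next
    }
    pred <- as.numeric(fit$intercept + d$X %*% fit$coefficients)
    resid <- pred - d$y
    rec$rmse[r] <- sqrt(mean(resid^2))
    rec$r2[r] <- if (r2_method == "pearson") {
      if (stats::sd(pred) > 0 && stats::sd(d$y) > 0) stats::cor(pred, d$y)^2 else NA_real_
    } else {
      sst <- sum((d$y - mean(d$y))^2)
      if (sst > 0) 1 - sum(resid^2) / sst else NA_real_
    }
    rec$vif[r] <- if (ncol(d$X) >= 2L) mean(vif(d$X)) else NA_real_
    for (i in test_idx) {
      rows <- d$site == ids[i]
      site_rmse_sum[ids[i]] <- site_rmse_sum[ids[i]] + sqrt(mean(resid[rows]^2))
      site_rmse_n[ids[i]] <- site_rmse_n[ids[i]] + 1L
    }
  }
  ok <- !is.na(rec$rmse)
  structure(list(
    rmse_mean = mean(rec$rmse[ok]), rmse_sd = stats::sd(rec$rmse[ok]),
    r2_mean = mean(rec$r2[ok], na.rm = TRUE),
    r2_sd = stats::sd(rec$r2[ok], na.rm = TRUE),
    vif_mean = mean(rec$vif[ok], na.rm = TRUE),
    vif_sd = stats::sd(rec$vif[ok], na.rm = TRUE),
    n_reps = sum(ok), n_discarded = n_discard,
    reps = rec[ok, , drop = FALSE],
    per_site = data.frame(site_id = ids,
                          rmse_mean = ifelse(site_rmse_n > 0,
                                             site_rmse_sum / site_rmse_n, NA_real_),
                          n_holdout = as.integer(site_rmse_n))),
    class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf(
    "<eval_summary> %d reps: RMSE %.3f +/- %.3f, r2 %.2f +/- %.2f, VIF %.2f +/- %.2f\n",
    x$n_reps, x$rmse_mean, x$rmse_sd, x$r2_mean, x$r2_sd, x$vif_mean, x$vif_sd))
  invisible(x)
}

#' Pearson correlation with a two-sided test
#'
#' Used to relate per-site summaries (e.g. soil-moisture importance vs MAP
#' or tree cover) across an ensemble.
#'
#' @param x,y Paired numeric vectors, n >= 3, finite, non-constant.
#' @return List with `r`, `p` (two-sided t-test) and `n`.
#' @export
importance_correlates <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Per-site phenometric errors of a fitted model
#'
#' Predicts NDVI per site, re-filters the modelled series with
#' [adaptive_savgol()] (observed aligned series are assumed already
#' smoothed by preprocessing), trims the lag burn-in from both series, and
#' compares SOS and amplitude.
#'
#' @param sites List of `aligned_series`.
#' @param model A `candidate_model`.
#' @param refilter_model Smooth the modelled series before comparison
#'   (default `TRUE`).
#' @param window,jump_threshold,small_window Passed to [adaptive_savgol()].
#' @param min_prominence_frac Passed to [start_of_season()].
#' @return `data.frame` with one row per site: `site_id`, `sos_error_steps`
#'   (mean over matched cycles; `NA` if none), `amplitude_error`,
#'   `n_cycles_matched`.
#' @export
phenometric_errors <- function(sites, model, refilter_model = TRUE,
                               window = 7L, jump_threshold = 0.08,
                               small_window = 3L, min_prominence_frac = 0.35) {
  rows <- lapply(sites, function(s) {
    pred <- predict_ndvi(model, s, pad = FALSE)$ndvi_pred
    obs <- s$ndvi[(nrow(s) - length(pred) + 1L):nrow(s)]
    if (refilter_model) {
      pred <- adaptive_savgol(pred, window = window,
                              jump_threshold = jump_threshold,
                              small_window = small_window)
    }
    cmp <- compare_phenometrics(pred, obs, min_prominence_frac)
    data.frame(site_id = attr(s, "site_id"),
               sos_error_steps = if (cmp$n_matched > 0) mean(cmp$sos_error) else NA_real_,
               amplitude_error = cmp$amplitude_error,
               n_cycles_matched = cmp$n_matched)
  })
  do.call(rbind, rows)
}
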