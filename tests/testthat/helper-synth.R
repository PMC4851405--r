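# Shared fixture builders. Everything is generated in code; no files.

# Small, fast ensemble for unit tests: 5 sites x 2 years, deterministic
# sampling unless noise/jitter requested.
quick_config <- function(n_sites = 5L, n_years = 2L, noise_sd = 0,
                         jitter = 0L, gap_fraction = 0, seed = 11L, ...) {
  synth_config(n_sites = n_sites, n_years = n_years, noise_sd = noise_sd,
               jitter = jitter, gap_fraction = gap_fraction, seed = seed, ...)
}

quick_aligned <- function(..., noise_free = TRUE) {
  aligned_truth(generate_ensemble(quick_config(...)), noise_free = noise_free)
}

# Hand-built aligned series with fully controlled columns.
manual_aligned <- function(ndvi, sm, dayl, site_id = "m1", map = 0.5,
                           start = as.Date("2010-01-01")) {
  n <- length(ndvi)
  aligned_series(
    data.frame(step_date = start + 8 * (seq_len(n) - 1L),
               ndvi = ndvi, sm = sm, dayl = dayl),
    site_id = site_id, map = map)
}

# Independent normal-equations OLS oracle (solve(X'X) X'y), never the QR path.
ols_oracle <- function(X, y) {
  Z <- cbind(1, as.matrix(X))
  beta <- solve(crossprod(Z), crossprod(Z, y))
  rss <- sum((y - Z %*% beta)^2)
  list(intercept = beta[1], coefficients = beta[-1], rss = rss,
       r2 = 1 - rss / sum((y - mean(y))^2))
}

# R^2 helper for importance oracles, independent of the package internals.
r2_oracle <- function(X, y) {
  if (is.null(X) || NCOL(X) == 0) return(0)
  f <- stats::lm.fit(cbind(1, as.matrix(X)), y)
  1 - sum(f$residuals^2) / sum((y - mean(y))^2)
}

expect_selected <- function(model, lags = c(2L, 2L),
                            transforms = c("log_map", "identity")) {
  vars <- vapply(model$terms, function(t) t$variable, character(1))
  ord <- order(vars)   # dayl, sm alphabetical; we pass sm-first args
  expect_setequal(vars, c("sm", "dayl"))
  got_lags <- vapply(model$terms, function(t) t$lag, integer(1))
  got_tr <- vapply(model$terms, function(t) t$transform, character(1))
  expect_equal(got_lags[match(c("sm", "dayl"), vars)], lags)
  expect_equal(got_tr[match(c("sm", "dayl"), vars)], transforms)
}
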