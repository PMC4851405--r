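# Exhaustive lagged-regression candidate search with BIC selection.
#
# The search space: at most one soil-moisture term (log(sm) or
# log(sm * MAP)) and at most one day-length term (identity), each lagged by
# 0..max_lag steps on the 8-day grid; fitted by pooled OLS across sites.

#' Specify one lagged regression term
#'
#' @param variable `"sm"` (volumetric soil moisture, %) or `"dayl"`
#'   (day length, hours).
#' @param transform `"log"` or `"log_map"` (natural log, the latter of
#'   `sm * MAP`) for soil moisture; `"identity"` for day length.
#' @param lag Non-negative integer lag in 8-day steps.
#' @param coefficient Optional known coefficient (used by the synthetic
#'   generator to plant a response).
#' @return A `term_spec` list.
#' @export
term_spec <- function(variable = c("sm", "dayl"),
                      transform = c("log", "log_map", "identity"),
                      lag = 0L, coefficient = NULL) {
  variable <- match.arg(variable)
  transform <- match.arg(transform)
  lag <- as.integer(lag)
  if (lag < 0L) stop("lag must be >= 0", call. = FALSE)
  if (variable == "sm" && !transform %in% c("log", "log_map")) {
    stop("sm terms use a log-family transform", call. = FALSE)
  }
  if (variable == "dayl" && transform != "identity") {
    stop("dayl terms use the identity transform", call. = FALSE)
  }
  structure(list(variable = variable, transform = transform, lag = lag,
                 coefficient = coefficient), class = "term_spec")
}

#' @export
format.term_spec <- function(x, ...) {
  switch(x$transform,
         log = sprintf("log(sm_%d)", x$lag),
         log_map = sprintf("log(sm_%d*MAP)", x$lag),
         identity = sprintf("dayL_%d", x$lag))
}

#' @export
print.term_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

model_label <- function(terms) paste(vapply(terms, format, character(1)),
                                     collapse = " + ")

#' Enumerate all candidate term combinations
#'
#' Every non-empty subset of \{one soil-moisture term, one day-length
#' term\}: the sm term ranges over 2 transforms x (max_lag + 1) lags, the
#' dayl term over (max_lag + 1) lags. With `max_lag = 10` this yields
#' 2*11 + 11 + 2*11*11 = 275 candidates.
#'
#' @param max_lag Maximum lag in 8-day steps (default 10, i.e. 80 days).
#' @return List of candidates; each candidate is a list of [term_spec()]s.
#' @export
enumerate_models <- function(max_lag = 10L) {
  max_lag <- as.integer(max_lag)
  stopifnot(max_lag >= 0L)
  sm_terms <- list()
  for (tr in c("log", "log_map")) for (l in 0:max_lag) {
    sm_terms[[length(sm_terms) + 1L]] <- term_spec("sm", tr, l)
  }
  dl_terms <- lapply(0:max_lag, function(l) term_spec("dayl", "identity", l))
  out <- c(lapply(sm_terms, list),
           lapply(dl_terms, list),
           unlist(lapply(sm_terms, function(s) lapply(dl_terms, function(d) list(s, d))),
                  recursive = FALSE))
  out
}

#' Build the pooled design for a candidate term set
#'
#' Per site, row t pairs `ndvi[t]` with each term's transformed regressor at
#' `t - lag`; the first `max(lag)` steps of every site are dropped so no row
#' lags across a site boundary; sites are stacked.
#'
#' @param sites List of `aligned_series` (need attributes `map`, `site_id`).
#' @param terms List of [term_spec()]s.
#' @return List with `y`, `X` (one column per term, labelled), `site`
#'   (factor of per-row site ids) and `max_lag`.
#' @export
build_design <- function(sites, terms) {
  stopifnot(length(sites) >= 1L, length(terms) >= 1L)
  max_lag <- max(vapply(terms, function(t) t$lag, integer(1)))
  ys <- list(); Xs <- list(); ids <- list()
  for (s in sites) {
    n <- nrow(s)
    if (n <= max_lag + 1L) {
      stop(sprintf("site %s (%d steps) shorter than max lag %d",
                   attr(s, "site_id"), n, max_lag), call. = FALSE)
    }
    map <- attr(s, "map")
    keep <- (max_lag + 1L):n
    cols <- lapply(terms, function(tm) {
      if (tm$variable == "sm" && any(s$sm <= 0)) {
        bad <- which(s$sm <= 0)[1L]
        stop(sprintf("non-positive soil moisture under log transform at site %s, step %d",
                     attr(s, "site_id"), bad), call. = FALSE)
      }
      x <- term_regressor(tm, s$sm, s$dayl, map)
      lag_vector(x, tm$lag)[keep]
    })
    X <- do.call(cbind, cols)
    colnames(X) <- vapply(terms, format, character(1))
    ys[[length(ys) + 1L]] <- s$ndvi[keep]
    Xs[[length(Xs) + 1L]] <- X
    ids[[length(ids) + 1L]] <- rep(attr(s, "site_id"), length(keep))
  }
  list(y = unlist(ys), X = do.call(rbind, Xs),
       site = factor(unlist(ids)), max_lag = max_lag)
}

#' Ordinary least squares with intercept
#'
#' QR-based least squares of `y` on `cbind(1, X)`. A rank-deficient design
#' is an error (distinct from near-collinearity, which fits and is reported
#' downstream via VIF).
#'
#' @param X Numeric regressor matrix (no intercept column).
#' @param y Response vector.
#' @return List with `intercept`, `coefficients` (named per column), `rss`,
#'   `r2` (= 1 - rss / total sum of squares about the mean) and `n`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("dimension mismatch", call. = FALSE)
  if (n <= p + 1L) stop("need more rows than coefficients + 1", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values in design", call. = FALSE)
  Z <- cbind(`(Intercept)` = 1, X)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("rank-deficient design", call. = FALSE)
  beta <- qr.coef(qz, y)
  res <- y - Z %*% beta
  rss <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) max(0, 1 - rss / sst) else 0
  list(intercept = unname(beta[1L]),
       coefficients = stats::setNames(beta[-1L], colnames(X)),
       rss = rss, r2 = r2, n = n)
}

#' Bayesian Information Criterion (Gaussian concentrated likelihood)
#'
#' `BIC = n * log(rss / n) + p * log(n)`, with `p` counting slope
#' coefficients plus the intercept; additive constants common to all
#' candidates are omitted. A perfect fit (`rss = 0`) returns `-Inf` so it
#' wins any comparison.
#'
#' @param rss Residual sum of squares (>= 0).
#' @param n_obs Number of observations (> n_params).
#' @param n_params Number of parameters, intercept included.
#' @return BIC score (dimensionless).
#' @export
bic <- function(rss, n_obs, n_params) {
  stopifnot(rss >= 0, n_obs > n_params)
  if (rss == 0) return(-Inf)
  n_obs * log(rss / n_obs) + n_params * log(n_obs)
}

# A numerically perfect fit leaves rss at floating-point dust (~1e-30);
# snapping it to exact zero lets the -Inf BIC sentinel and the parsimony
# tie-break decide instead of rounding noise.
snap_rss <- function(rss, y) {
  if (rss <= 1e-12 * max(sum(y^2), .Machine$double.xmin)) 0 else rss
}

#' Exhaustive BIC model selection over all lagged candidates
#'
#' Fits every candidate from [enumerate_models()] on the pooled design and
#' returns the lowest-BIC fit. Ties are broken by fewer parameters, then by
#' smaller total lag. The full ranking is kept for inspection.
#'
#' @param sites List of `aligned_series`.
#' @param max_lag Maximum lag in 8-day steps (default 10).
#' @return A `candidate_model`: list with `terms`, `coefficients`,
#'   `intercept`, `rss`, `r2`, `bic`, `n_obs` and a `ranking` data frame
#'   over all candidates.
#' @export
select_model <- function(sites, max_lag = 10L) {
  stopifnot(length(sites) >= 1L)
  cands <- enumerate_models(max_lag)
  nc <- length(cands)
  fits <- vector("list", nc)
  stats_df <- data.frame(model = character(nc), n_terms = integer(nc),
                         total_lag = integer(nc), rss = numeric(nc),
                         r2 = numeric(nc), bic = numeric(nc),
                         n_obs = integer(nc), stringsAsFactors = FALSE)
  for (i in seq_len(nc)) {
    terms <- cands[[i]]
    d <- build_design(sites, terms)
    f <- fit_ols(d$X, d$y)
    f$rss <- snap_rss(f$rss, d$y)
    b <- bic(f$rss, f$n, length(terms) + 1L)
    fits[[i]] <- f
    stats_df$model[i] <- model_label(terms)
    stats_df$n_terms[i] <- length(terms)
    stats_df$total_lag[i] <- sum(vapply(terms, function(t) t$lag, integer(1)))
    stats_df$rss[i] <- f$rss
    stats_df$r2[i] <- f$r2
    stats_df$bic[i] <- b
    stats_df$n_obs[i] <- f$n
  }
  ord <- order(stats_df$bic, stats_df$n_terms, stats_df$total_lag)
  best <- ord[1L]
  f <- fits[[best]]
  structure(list(terms = cands[[best]],
                 coefficients = f$coefficients,
                 intercept = f$intercept,
                 rss = f$rss, r2 = f$r2, bic = stats_df$bic[best],
                 n_obs = f$n, max_lag = as.integer(max_lag),
                 ranking = stats_df[ord, , drop = FALSE]),
            class = "candidate_model")
}

#' Refit a fixed term specification on (a subset of) sites
#'
#' Keeps the selected model structure and re-estimates coefficients, as the
#' resampling evaluations require.
#'
#' @param sites List of `aligned_series`.
#' @param terms List of [term_spec()]s (or a `candidate_model`).
#' @return Same shape as [select_model()]'s return, without the ranking.
#' @export
refit_model <- function(sites, terms) {
  if (inherits(terms, "candidate_model")) terms <- terms$terms
  d <- build_design(sites, terms)
  f <- fit_ols(d$X, d$y)
  f$rss <- snap_rss(f$rss, d$y)
  structure(list(terms = terms, coefficients = f$coefficients,
                 intercept = f$intercept, rss = f$rss, r2 = f$r2,
                 bic = bic(f$rss, f$n, length(terms) + 1L), n_obs = f$n),
            class = "candidate_model")
}

#' Predict NDVI for one site from a fitted model
#'
#' @param model A `candidate_model`.
#' @param site An `aligned_series`.
#' @param pad If `TRUE` (default), return a full-length series with `NA`
#'   for the first `max(lag)` steps so predictions share the site's grid.
#' @return `data.frame` with `step_date` and `ndvi_pred`.
#' @export
predict_ndvi <- function(model, site, pad = TRUE) {
  d <- build_design(list(site), model$terms)
  pred <- as.numeric(model$intercept + d$X %*% model$coefficients)
  if (pad) {
    out <- rep(NA_real_, nrow(site))
    out[(d$max_lag + 1L):nrow(site)] <- pred
    data.frame(step_date = site$step_date, ndvi_pred = out)
  } else {
    data.frame(step_date = site$step_date[(d$max_lag + 1L):nrow(site)],
               ndvi_pred = pred)
  }
}

#' @export
print.candidate_model <- function(x, ...) {
  cat("<candidate_model>\n  NDVI =",
      paste(sprintf("%.4g*%s", x$coefficients,
                    vapply(x$terms, format, character(1))), collapse = " + "),
      sprintf("+ %.4g", x$intercept), "\n")
  cat(sprintf("  n = %d, r2 = %.3f, BIC = %.1f\n", x$n_obs, x$r2, x$bic))
  invisible(x)
}
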