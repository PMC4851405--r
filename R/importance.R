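# Relative importance of soil moisture vs day length per site: r-squared
# decomposition by averaging incremental contributions over regressor
# orderings, with all lags 0..max_lag of a variable bundled into one group.

# R^2 of y on X (with intercept); ncol(X) == 0 gives 0. Rank deficiency is
# tolerated here (qr.coef drops aliased columns via NA -> treated as 0),
# since subset R^2 is well defined regardless.
r_squared <- function(X, y) {
  if (is.null(X) || ncol(as.matrix(X)) == 0L) return(0)
  Z <- cbind(1, as.matrix(X))
  qz <- qr(Z)
  fit <- qr.fitted(qz, y)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(0)
  max(0, 1 - sum((y - fit)^2) / sst)
}

#' Grouped average-over-orderings importance for one site
#'
#' Builds the within-site design with group A = log(sm) at lags
#' 0..`max_lag` and group B = day length at lags 0..`max_lag` (soil moisture
#' enters without the MAP factor: within one site MAP is constant, so the
#' choice only shifts the intercept and cannot change any R^2). With two
#' groups the average over the two group orderings is exact:
#' `I(A) = (R2(A) + R2(A+B) - R2(B)) / 2` and symmetrically for B, so
#' `I(A) + I(B) = R2(A+B)`. Reported as percentages of the decomposed R^2.
#'
#' @param site An `aligned_series`.
#' @param max_lag Lags bundled per variable (default 10).
#' @return An `importance_result`: list with `site_id`, `sm_importance`,
#'   `dayl_importance` (percent, summing to 100), `total_r2`, and the raw
#'   group contributions `I_sm`, `I_dayl`.
#' @export
group_lmg <- function(site, max_lag = 10L) {
  max_lag <- as.integer(max_lag)
  n <- nrow(site)
  need <- 2L * (max_lag + 1L) + max_lag + 2L
  if (n < need) {
    stop(sprintf("site %s too short (%d steps) for max_lag %d (need >= %d)",
                 attr(site, "site_id"), n, max_lag, need), call. = FALSE)
  }
  if (any(site$sm <= 0)) stop("non-positive soil moisture under log", call. = FALSE)
  keep <- (max_lag + 1L):n
  y <- site$ndvi[keep]
  lag_block <- function(x) {
    do.call(cbind, lapply(0:max_lag, function(l) lag_vector(x, l)[keep]))
  }
  A <- lag_block(log(site$sm))
  B <- lag_block(site$dayl)
  r2A <- r_squared(A, y)
  r2B <- r_squared(B, y)
  r2AB <- r_squared(cbind(A, B), y)
  if (r2AB <= 0) {
    stop(sprintf("full-model R^2 is zero at site %s; importance undefined",
                 attr(site, "site_id")), call. = FALSE)
  }
  IA <- (r2A + r2AB - r2B) / 2
  IB <- (r2B + r2AB - r2A) / 2
  for (v in c("IA", "IB")) {
    val <- get(v)
    if (val < 0) {
      warning(sprintf("numerically negative group contribution (%s = %.3g) at site %s",
                      v, val, attr(site, "site_id")), call. = FALSE)
    }
  }
  structure(list(site_id = attr(site, "site_id"),
                 sm_importance = 100 * IA / r2AB,
                 dayl_importance = 100 * IB / r2AB,
                 total_r2 = r2AB, I_sm = IA, I_dayl = IB),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("<importance_result> %s: sm %.1f%%, dayL %.1f%% of r2 = %.3f\n",
              x$site_id, x$sm_importance, x$dayl_importance, x$total_r2))
  invisible(x)
}

#' Classical per-regressor LMG decomposition (small designs)
#'
#' Exact average over all `m!` orderings of each regressor's incremental
#' R^2, computed through the `2^m`-subset identity with weights
#' `|S|! (m-|S|-1)! / m!`. Refuses designs wider than 12 columns; use
#' [group_lmg()] for the bundled two-group decomposition at full width.
#'
#' @param X Regressor matrix, `m <= 12` columns.
#' @param y Response vector.
#' @param groups Optional list of column-index vectors; if given, per-group
#'   sums are returned alongside the per-regressor contributions.
#' @return List with `contributions` (named, summing to the full-model R^2),
#'   `total_r2`, and optionally `group_sums`.
#' @export
individual_lmg <- function(X, y, groups = NULL) {
  X <- as.matrix(X)
  m <- ncol(X)
  if (m > 12L) {
    stop("individual_lmg enumerates 2^m subsets; m > 12 is refused - use group_lmg",
         call. = FALSE)
  }
  stopifnot(m >= 1L, nrow(X) == length(y))
  n_sub <- bitwShiftL(1L, m)
  r2s <- numeric(n_sub)
  popcount <- integer(n_sub)
  for (mask in seq_len(n_sub) - 1L) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
    popcount[mask + 1L] <- length(idx)
    r2s[mask + 1L] <- r_squared(X[, idx, drop = FALSE], y)
  }
  lfac <- lfactorial(0:m)
  w <- exp(lfac[0:(m - 1L) + 1L] + lfac[(m - 1L):0 + 1L] - lfac[m + 1L])
  contrib <- numeric(m)
  for (j in seq_len(m)) {
    bj <- bitwShiftL(1L, j - 1L)
    for (mask in seq_len(n_sub) - 1L) {
      if (bitwAnd(mask, bj) == 0L) {
        s <- popcount[mask + 1L]
        contrib[j] <- contrib[j] +
          w[s + 1L] * (r2s[bitwOr(mask, bj) + 1L] - r2s[mask + 1L])
      }
    }
  }
  names(contrib) <- colnames(X) %||% paste0("x", seq_len(m))
  out <- list(contributions = contrib, total_r2 = r2s[n_sub])
  if (!is.null(groups)) {
    out$group_sums <- vapply(groups, function(g) sum(contrib[g]), numeric(1))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
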