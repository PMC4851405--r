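# Brute-force oracle for the grouped decomposition: average the incremental
# R^2 of each group over the two possible group orderings.
group_lmg_oracle <- function(A, B, y) {
  r2A <- r2_oracle(A, y); r2B <- r2_oracle(B, y)
  r2AB <- r2_oracle(cbind(A, B), y)
  IA <- mean(c(r2A - 0, r2AB - r2B))       # A first, A second
  IB <- mean(c(r2AB - r2A, r2B - 0))
  list(IA = IA, IB = IB, r2AB = r2AB)
}

lag_block <- function(x, max_lag) {
  n <- length(x)
  keep <- (max_lag + 1):n
  do.call(cbind, lapply(0:max_lag, function(l) {
    xl <- if (l == 0) x else c(rep(NA, l), x[1:(n - l)])
    xl[keep]
  }))
}

test_that("grouped decomposition matches the ordering brute force", {
  set.seed(5)
  for (i in 1:5) {
    n <- 120
    t <- seq_len(n)
    sm <- pmax(0.5, 12 + 9 * sin(2 * pi * t / 46) + stats::rnorm(n))
    dayl <- 12 + 2.5 * sin(2 * pi * (t - 3) / 46)
    ndvi <- 0.3 + 0.05 * log(sm) + 0.012 * dayl + stats::rnorm(n, 0, 0.03)
    site <- manual_aligned(ndvi, sm, dayl)
    L <- 3
    res <- group_lmg(site, max_lag = L)
    keep <- (L + 1):n
    o <- group_lmg_oracle(lag_block(log(sm), L), lag_block(dayl, L), ndvi[keep])
    expect_equal(res$I_sm, o$IA, tolerance = 1e-10)
    expect_equal(res$I_dayl, o$IB, tolerance = 1e-10)
    expect_equal(res$total_r2, o$r2AB, tolerance = 1e-10)
    # decomposition identity and percentage closure
    expect_equal(res$I_sm + res$I_dayl, res$total_r2, tolerance = 1e-10)
    expect_equal(res$sm_importance + res$dayl_importance, 100, tolerance = 1e-9)
  }
})

test_that("orthogonal groups give marginal R^2 as their contribution", {
  set.seed(8)
  n <- 200
  A <- matrix(stats::rnorm(n), n, 1)
  B <- matrix(stats::rnorm(n), n, 1)
  A <- A - mean(A); B <- B - mean(B)
  B <- B - A * sum(A * B) / sum(A * A)      # exactly orthogonal, centred
  y <- 0.7 * A[, 1] + 0.3 * B[, 1] + stats::rnorm(n, 0, 0.2)
  # with orthogonal regressors incremental R^2 does not depend on position
  o <- group_lmg_oracle(A, B, y)
  expect_equal(o$IA, r2_oracle(A, y), tolerance = 1e-10)
  expect_equal(o$IB, r2_oracle(B, y), tolerance = 1e-10)
})

test_that("individual LMG agrees with factorial enumeration at m = 3", {
  set.seed(13)
  n <- 60
  X <- matrix(stats::rnorm(3 * n), n, 3)
  X[, 2] <- X[, 2] + 0.6 * X[, 1]           # some collinearity
  y <- X %*% c(1, 0.5, -0.3) + stats::rnorm(n)
  res <- individual_lmg(X, y)

  orderings <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  contrib <- numeric(3)
  for (ord in orderings) {
    prev <- 0
    for (k in seq_along(ord)) {
      r2 <- r2_oracle(X[, ord[1:k], drop = FALSE], y)
      contrib[ord[k]] <- contrib[ord[k]] + (r2 - prev) / length(orderings)
      prev <- r2
    }
  }
  expect_equal(unname(res$contributions), contrib, tolerance = 1e-10)
  expect_equal(sum(res$contributions), res$total_r2, tolerance = 1e-10)
})

test_that("individual LMG degenerate and guard cases", {
  set.seed(14)
  x <- stats::rnorm(40)
  y <- 2 * x + stats::rnorm(40, 0, 0.5)
  r1 <- individual_lmg(matrix(x), y)
  expect_equal(unname(r1$contributions), r2_oracle(matrix(x), y))

  # two orthogonal columns: each gets its marginal R^2
  a <- stats::rnorm(100); a <- a - mean(a)
  b <- stats::rnorm(100); b <- b - mean(b); b <- b - a * sum(a * b) / sum(a^2)
  yy <- a + 0.5 * b + stats::rnorm(100, 0, 0.3)
  r2 <- individual_lmg(cbind(a = a, b = b), yy)
  expect_equal(unname(r2$contributions),
               c(r2_oracle(matrix(a), yy), r2_oracle(matrix(b), yy)),
               tolerance = 1e-10)

  expect_error(individual_lmg(matrix(stats::rnorm(13 * 30), 30, 13),
                              stats::rnorm(30)), "group_lmg")

  # group sums surface per-group totals
  r3 <- individual_lmg(cbind(a = a, b = b), yy, groups = list(g1 = 1, g2 = 2))
  expect_equal(unname(r3$group_sums), unname(r2$contributions))
})

test_that("importance is invariant to rescaling soil moisture (MAP factor)", {
  al <- quick_aligned(n_sites = 1, noise_sd = 0.02, noise_free = FALSE)[[1]]
  a1 <- group_lmg(al, max_lag = 4)
  al2 <- al
  al2$sm <- al2$sm * 3.7          # log(c * sm) = log c + log sm
  a2 <- group_lmg(al2, max_lag = 4)
  expect_equal(a1$sm_importance, a2$sm_importance, tolerance = 1e-8)
  expect_equal(a1$total_r2, a2$total_r2, tolerance = 1e-8)
})

test_that("site-level importance on the default ensemble decomposes r2", {
  al <- quick_aligned(n_sites = 3, n_years = 3, noise_sd = 0.02,
                      noise_free = FALSE)
  for (a in al) {
    r <- group_lmg(a)
    expect_equal(r$I_sm + r$I_dayl, r$total_r2, tolerance = 1e-10)
    expect_gte(r$I_sm, -1e-10)
    expect_gte(r$I_dayl, -1e-10)
    expect_true(r$total_r2 > 0 && r$total_r2 <= 1)
  }
  short <- manual_aligned(stats::runif(20, 0.2, 0.6), rep(10, 20), rep(12, 20))
  expect_error(group_lmg(short, max_lag = 10), "too short")
})
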