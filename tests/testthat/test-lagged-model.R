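test_that("candidate enumeration matches the closed form", {
  expect_equal(length(enumerate_models(10)), 275L)
  expect_equal(length(enumerate_models(0)), 5L)
  for (L in 0:10) {
    expect_equal(length(enumerate_models(L)),
                 2L * (L + 1L) + (L + 1L) + 2L * (L + 1L)^2)
  }
  # at most one term per variable, transforms respect the search space
  for (cand in enumerate_models(3)) {
    vars <- vapply(cand, function(t) t$variable, character(1))
    expect_equal(anyDuplicated(vars), 0L)
    for (t in cand) {
      if (t$variable == "sm") expect_true(t$transform %in% c("log", "log_map"))
      if (t$variable == "dayl") expect_equal(t$transform, "identity")
    }
  }
})

test_that("term_spec rejects transforms outside the search space", {
  expect_error(term_spec("sm", "identity"), "log-family")
  expect_error(term_spec("dayl", "log"), "identity")
  expect_error(term_spec("sm", "log", -1), ">= 0")
})

test_that("design building trims lags per site and never leaks across sites", {
  n <- 100
  s1 <- manual_aligned(seq(0.2, 0.6, length.out = n), rep(10, n), rep(12, n))
  spec2 <- list(term_spec("sm", "log", 2))
  d <- build_design(list(s1), spec2)
  expect_equal(length(d$y), 98L)

  # sentinel: site 2's first sm values are extreme; if lags leaked across
  # the site boundary they would surface in site 1's tail rows
  s2 <- manual_aligned(rep(0.4, 50), c(90, 90, rep(10, 48)), rep(12, 50),
                       site_id = "m2")
  d12 <- build_design(list(s1, s2), spec2)
  expect_equal(length(d12$y), 98L + 48L)
  d1 <- build_design(list(s1), spec2)
  d2 <- build_design(list(s2), spec2)
  expect_equal(unname(d12$X[, 1]), unname(c(d1$X[, 1], d2$X[, 1])))
  expect_equal(sum(d12$X[d12$site == "m2", 1] == log(90)), 2L)

  # log(sm * MAP) arithmetic: sm 10 vol%, MAP 0.5 m/yr -> ln(5)
  s3 <- manual_aligned(rep(0.4, 20), rep(10, 20), rep(12, 20), map = 0.5)
  d3 <- build_design(list(s3), list(term_spec("sm", "log_map", 0)))
  expect_equal(unname(d3$X[1, 1]), log(5))
})

test_that("OLS matches hand examples and a normal-equations oracle", {
  f <- fit_ols(matrix(0:2), c(1, 2, 3))
  expect_equal(unname(f$coefficients), 1)
  expect_equal(f$intercept, 1)
  expect_equal(f$rss, 0)
  expect_equal(f$r2, 1)

  # y orthogonal to centred x: slope 0, r2 0
  f0 <- fit_ols(matrix(c(-1, 0, 1, 0)), c(0, 1, 0, 1))
  expect_equal(unname(f0$coefficients), 0)
  expect_equal(f0$r2, 0)

  set.seed(99)
  for (i in 1:100) {
    X <- matrix(stats::rnorm(100), 50, 2)
    y <- stats::rnorm(50)
    f <- fit_ols(X, y)
    o <- ols_oracle(X, y)
    expect_equal(unname(f$coefficients), unname(as.numeric(o$coefficients)),
                 tolerance = 1e-8)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-8)
    expect_equal(f$rss, o$rss, tolerance = 1e-8)
  }

  X <- cbind(1:10, 2 * (1:10))
  expect_error(fit_ols(X, stats::rnorm(10)), "rank-deficient")
})

test_that("BIC arithmetic, monotonicity and the perfect-fit sentinel", {
  expect_equal(bic(1, 100, 3), 100 * log(1 / 100) + 3 * log(100))
  expect_lt(bic(0.5, 50, 3), bic(1.0, 50, 3))   # lower rss wins at equal p
  expect_lt(bic(1, 50, 2), bic(1, 50, 3))       # fewer params win at equal rss
  expect_identical(bic(0, 100, 3), -Inf)
  expect_error(bic(1, 3, 3))
})

test_that("noise-free selection recovers the planted model exactly", {
  al <- quick_aligned()
  m <- select_model(al)
  expect_selected(m)
  expect_equal(unname(m$coefficients[vapply(m$terms, function(t) t$variable,
                                            character(1)) == "sm"]),
               0.12, tolerance = 1e-6)
  expect_equal(unname(m$coefficients[vapply(m$terms, function(t) t$variable,
                                            character(1)) == "dayl"]),
               0.01, tolerance = 1e-6)
  expect_equal(m$intercept, 0.22, tolerance = 1e-6)
  expect_identical(m$bic, -Inf)
  expect_equal(nrow(m$ranking), 275L)
})

test_that("parsimony: a single-variable plant rejects two-term candidates", {
  cfg <- quick_config(true_terms = list(term_spec("sm", "log_map", 2,
                                                  coefficient = 0.12)),
                      seed = 31)
  m <- select_model(aligned_truth(generate_ensemble(cfg), noise_free = TRUE))
  expect_equal(length(m$terms), 1L)
  expect_equal(m$terms[[1]]$variable, "sm")
  expect_equal(m$terms[[1]]$lag, 2L)
  expect_equal(m$terms[[1]]$transform, "log_map")
  expect_equal(unname(m$coefficients), 0.12, tolerance = 1e-6)
})

test_that("selection consistency holds as noise shrinks", {
  for (ns in c(0.01, 0)) {
    cfg <- quick_config(n_sites = 8, n_years = 3, noise_sd = ns, seed = 77)
    m <- select_model(aligned_truth(generate_ensemble(cfg),
                                    noise_free = (ns == 0)))
    expect_selected(m)
  }
})

test_that("prediction pads the lag burn-in and matches the fit", {
  al <- quick_aligned(n_sites = 2)
  m <- select_model(al)
  p <- predict_ndvi(m, al[[1]])
  expect_equal(nrow(p), nrow(al[[1]]))
  expect_true(all(is.na(p$ndvi_pred[1:2])))
  expect_equal(p$ndvi_pred[-(1:2)], al[[1]]$ndvi[-(1:2)], tolerance = 1e-8)
})
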