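test_that("day length: equator, polar clamp, and an independent solar oracle", {
  dates <- as.Date("2010-01-01") + seq(0, 360, by = 30)
  expect_true(all(abs(day_length(0, dates) - 12) < 0.05))
  expect_equal(day_length(80, as.Date("2010-06-21")), 24)
  expect_equal(day_length(80, as.Date("2010-12-21")), 0)

  # Oracle: Spencer (1971) Fourier declination + the same hour-angle
  # geometry; independent of the Cooper form used by day_length().
  spencer_daylen <- function(lat, date) {
    doy <- as.POSIXlt(date)$yday + 1
    g <- 2 * pi * (doy - 1) / 365
    decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
      0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
      0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
    co <- pmin(1, pmax(-1, -tan(lat * pi / 180) * tan(decl)))
    24 * acos(co) / pi
  }
  probe <- as.Date(c("2010-06-21", "2010-03-20", "2010-09-22", "2010-12-21"))
  for (d in seq_along(probe)) {
    expect_lt(abs(day_length(38.43, probe[d]) - spencer_daylen(38.43, probe[d])),
              0.2)
  }
})

test_that("gap-fill / resample preserves lines and interpolates midpoints", {
  d0 <- as.Date("2010-01-01")
  obs_d <- d0 + c(0, 16)
  expect_equal(gapfill_resample(obs_d, c(0.2, 0.4))$ndvi, c(0.2, 0.3, 0.4))

  set.seed(1)
  dd <- d0 + sort(sample(0:200, 12))
  line <- 0.1 + 0.002 * as.numeric(dd - d0)
  gf <- gapfill_resample(dd, line)
  expect_equal(gf$ndvi, 0.1 + 0.002 * as.numeric(gf$step_date - d0),
               tolerance = 1e-12)
  expect_true(all(gf$step_date >= dd[1] & gf$step_date <= dd[length(dd)]))
  expect_error(gapfill_resample(d0, 0.5), "at least 2")
})

test_that("adaptive Savitzky-Golay reproduces polynomials and honours the jump rule", {
  expect_equal(adaptive_savgol(rep(0.3, 20)), rep(0.3, 20))
  t <- 1:25
  quad <- 0.2 + 0.01 * t - 3e-4 * t^2
  expect_equal(adaptive_savgol(quad), quad, tolerance = 1e-10)

  # step 0.2 -> 0.5 exceeds the 0.08 threshold: the two points flanking the
  # step must use the 3-point window, whose degree-2 fit interpolates the 3
  # points exactly, i.e. returns the raw value
  x <- c(rep(0.2, 10), rep(0.5, 10))
  sg <- adaptive_savgol(x)
  expect_equal(sg[10], x[10])
  expect_equal(sg[11], x[11])
  # away from the step the 7-point fit is in charge and moves the shoulder
  expect_false(isTRUE(all.equal(sg[8], x[8])))
  expect_error(adaptive_savgol(x, window = 6), "odd")
  expect_error(adaptive_savgol(x[1:5], window = 7), "shorter")
})

test_that("filter is idempotent on random polynomials of degree <= 2", {
  set.seed(42)
  for (i in 1:20) {
    cf <- stats::rnorm(3, 0, c(0.5, 0.02, 0.0005))
    t <- seq_len(30)
    p <- cf[1] + cf[2] * t + cf[3] * t^2
    expect_equal(adaptive_savgol(p, jump_threshold = Inf), p, tolerance = 1e-9)
  }
})

test_that("climate aggregation takes window medians and maxima", {
  d0 <- as.Date("2010-06-15")
  clim <- data.frame(date = d0 + 0:15, sm_volpct = c(rep(7, 8), 1:7, 100))
  agg <- aggregate_climate(clim, latitude = 40, grid_dates = c(d0, d0 + 8))
  expect_equal(agg$sm, c(7, 4.5))
  expect_equal(agg$dayl, c(max(day_length(40, d0 + 0:7)),
                           max(day_length(40, d0 + 8:15))))
  expect_error(aggregate_climate(clim, 40, d0 + 30), "no daily climate")

  # a northern site's annual day-length maximum falls in the solstice window
  year <- data.frame(date = as.Date("2010-01-01") + 0:364, sm_volpct = 10)
  grid <- as.Date("2010-01-01") + seq(0, 360, by = 8)
  ag <- aggregate_climate(year, 45, grid)
  peak_step <- grid[which.max(ag$dayl)]
  expect_true(abs(as.numeric(peak_step - as.Date("2010-06-21"))) <= 8)
})

test_that("aggregation and resampling stay within the convex hull of inputs", {
  cfg <- quick_config(n_sites = 2, noise_sd = 0.02, jitter = 6L)
  for (s in generate_ensemble(cfg)) {
    gf <- gapfill_resample(s$ndvi$acq_date, s$ndvi$ndvi)
    expect_true(all(gf$ndvi >= min(s$ndvi$ndvi) - 1e-12 &
                      gf$ndvi <= max(s$ndvi$ndvi) + 1e-12))
    agg <- aggregate_climate(s$climate, s$latitude, gf$step_date)
    expect_true(all(agg$sm >= min(s$climate$sm_volpct) &
                      agg$sm <= max(s$climate$sm_volpct)))
    al <- align_site(s)
    expect_equal(nrow(al), length(al$sm))
    expect_false(anyNA(al$ndvi) || anyNA(al$sm) || anyNA(al$dayl))
  }
})

test_that("gap-filled grid tracks the latent daily series under jitter", {
  cfg <- quick_config(n_sites = 1, noise_sd = 0, jitter = 7L,
                      gap_fraction = 0.05, seed = 21)
  s <- generate_site(cfg, 1)
  gf <- gapfill_resample(s$ndvi$acq_date, s$ndvi$ndvi)
  truth <- s$aligned
  # the jittered grid is offset from the generation grid; interpolate the
  # latent truth onto it for comparison
  b <- stats::approx(as.numeric(truth$step_date), truth$ndvi_true,
                     xout = as.numeric(gf$step_date), rule = 2)$y
  # linear interpolation across <= 32-day gaps of a smooth seasonal signal
  expect_lt(max(abs(gf$ndvi - b)), 0.06)
  expect_lt(mean(abs(gf$ndvi - b)), 0.015)
})

test_that("variable screening drops the collinear low-correlation member", {
  set.seed(7)
  mk <- function() {
    # soil moisture aseasonal so the only collinear pair is dayl ~ tmin,
    # with tmin the noisier (lower NDVI correlation) member
    n <- 80
    t <- seq_len(n)
    dayl <- 12 + 2 * sin(2 * pi * t / 46)
    tmin <- 15 + 1.8 * sin(2 * pi * t / 46) + stats::rnorm(n, 0, 0.9)
    sm <- 10 + stats::rnorm(n, 0, 2)
    ndvi <- 0.3 + 0.02 * sm + 0.015 * dayl + stats::rnorm(n, 0, 0.02)
    data.frame(ndvi = ndvi, sm = sm, dayl = dayl, tmin = tmin)
  }
  tabs <- replicate(6, mk(), simplify = FALSE)
  sc <- screen_variables(tabs, candidates = c("sm", "dayl", "tmin"))
  expect_gt(sc$mutual["dayl", "tmin"], 0.7)
  expect_true("tmin" %in% sc$dropped)
  expect_setequal(sc$retained, c("sm", "dayl"))

  # duplicated variable: exactly one survives
  tabs2 <- lapply(tabs, function(tb) transform(tb, dayl2 = dayl))
  sc2 <- screen_variables(tabs2, candidates = c("dayl", "dayl2"))
  expect_equal(length(sc2$retained), 1L)

  # single variable passes through untouched
  sc3 <- screen_variables(tabs, candidates = "sm")
  expect_equal(sc3$retained, "sm")

  # constant series is flagged and dropped
  tabs4 <- lapply(tabs, function(tb) transform(tb, flat = 1))
  expect_warning(sc4 <- screen_variables(tabs4, candidates = c("sm", "flat")),
                 "constant")
  expect_false("flat" %in% sc4$retained)
})
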