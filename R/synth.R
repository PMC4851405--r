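# Synthetic site ensembles: pulsed soil moisture, solar day length, and a
# lagged log-linear NDVI response sampled like 16-day satellite composites.

# mm of rain spread over this surface-soil depth converts to volumetric %
.SOIL_DEPTH_MM <- 300
.SM_EPS <- 0.1   # volumetric % floor keeping log transforms finite

#' Configuration for the synthetic site generator
#'
#' The defaults state the simulated world once: 15 sites over 3 years (the
#' study design this package emulates), savannah-like latitudes and mean
#' annual precipitation, a 120-ish-day wet season, and an NDVI response
#' planted with the canonical two-term structure
#' `0.12 * log(sm_lag2 * MAP) + 0.01 * dayL_lag2 + 0.22`.
#'
#' @param n_sites Number of sites.
#' @param n_years Years of daily climate per site.
#' @param latitude_range Degrees, drawn uniformly per site.
#' @param map_range Mean annual precipitation range in m/year.
#' @param wet_season_doy Wet-season day-of-year window (northern-hemisphere
#'   calendar; mirrored by half a year for southern sites).
#' @param rain_rate Expected rain events per wet-season day.
#' @param event_depth_mean Mean event depth in mm (exponential depths).
#' @param sm_decay Fractional soil-moisture loss per day, in (0, 1).
#' @param sm_field_capacity Upper clamp, volumetric %, in (0, 100\].
#' @param sm_residual Residual volumetric % the store cannot drain below
#'   (default 3, typical of savannah surface soils; the hard floor is
#'   0.1 vol% regardless, keeping log transforms finite).
#' @param true_terms List of [term_spec()]s with a `coefficient` entry each;
#'   the planted NDVI response.
#' @param intercept Planted intercept, NDVI units.
#' @param noise_sd NDVI observation noise standard deviation (>= 0). The
#'   paper gives no MODIS noise magnitude; 0.02 is a configurable guess.
#' @param composite_period Compositing window in days (default 16).
#' @param jitter Maximum acquisition-date offset inside a composite window.
#' @param gap_fraction Fraction of composites removed at random, in \[0, 1).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_sites = 15L, n_years = 3L,
                         latitude_range = c(-26, 40),
                         map_range = c(0.3, 1.2),
                         wet_season_doy = c(152L, 273L),
                         rain_rate = 0.3,
                         event_depth_mean = 12,
                         sm_decay = 0.04,
                         sm_field_capacity = 45,
                         sm_residual = 3,
                         true_terms = list(
                           term_spec("sm", "log_map", 2L, coefficient = 0.12),
                           term_spec("dayl", "identity", 2L, coefficient = 0.01)),
                         intercept = 0.22,
                         noise_sd = 0.02,
                         composite_period = 16L,
                         jitter = 8L,
                         gap_fraction = 0.05,
                         seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites), n_years = as.integer(n_years),
              latitude_range = latitude_range, map_range = map_range,
              wet_season_doy = as.integer(wet_season_doy),
              rain_rate = rain_rate, event_depth_mean = event_depth_mean,
              sm_decay = sm_decay, sm_field_capacity = sm_field_capacity,
              sm_residual = sm_residual,
              true_terms = true_terms, intercept = intercept,
              noise_sd = noise_sd,
              composite_period = as.integer(composite_period),
              jitter = as.integer(jitter), gap_fraction = gap_fraction,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(cfg$n_sites >= 1L, "n_sites must be >= 1")
  chk(cfg$n_years >= 1L, "n_years must be >= 1")
  chk(diff(cfg$latitude_range) > 0 && all(abs(cfg$latitude_range) <= 90),
      "latitude_range must be non-degenerate within [-90, 90]")
  chk(diff(cfg$map_range) > 0 && all(cfg$map_range > 0),
      "map_range must be non-degenerate and positive (m/year)")
  chk(cfg$rain_rate >= 0, "rain_rate must be >= 0")
  chk(cfg$event_depth_mean > 0, "event_depth_mean must be > 0")
  chk(cfg$sm_decay > 0 && cfg$sm_decay < 1, "sm_decay must lie in (0, 1)")
  chk(cfg$sm_field_capacity > 0 && cfg$sm_field_capacity <= 100,
      "sm_field_capacity must lie in (0, 100]")
  chk(cfg$sm_residual >= 0 && cfg$sm_residual < cfg$sm_field_capacity,
      "sm_residual must lie in [0, sm_field_capacity)")
  chk(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(cfg$composite_period >= 1L, "composite_period must be >= 1")
  chk(cfg$jitter >= 0L && cfg$jitter < cfg$composite_period,
      "jitter must satisfy 0 <= jitter < composite_period")
  chk(cfg$gap_fraction >= 0 && cfg$gap_fraction < 1,
      "gap_fraction must lie in [0, 1)")
  for (tm in cfg$true_terms) {
    chk(inherits(tm, "term_spec"), "true_terms must be term_spec objects")
    chk(tm$lag >= 0L && tm$lag <= 10L, "true term lag must lie in [0, 10]")
    chk(!is.null(tm$coefficient), "true terms need a coefficient")
  }
  invisible(cfg)
}

# doy membership in a possibly wrapping [start, end] window
in_doy_window <- function(doy, window) {
  if (window[1] <= window[2]) doy >= window[1] & doy <= window[2]
  else doy >= window[1] | doy <= window[2]
}

shift_window_south <- function(window, latitude) {
  if (latitude >= 0) return(window)
  (window + 182L - 1L) %% 365L + 1L
}

#' Simulate daily rainfall as a wet-season Poisson pulse process
#'
#' Events arrive as a Poisson process with `rain_rate` events per day,
#' restricted to the wet-season day-of-year window; depths are exponential
#' with mean `event_depth_mean`.
#'
#' @param n_days Number of days.
#' @param start_date First day (`Date`).
#' @param wet_window Integer day-of-year window (wraps across new year).
#' @param rain_rate Expected events per wet-season day.
#' @param event_depth_mean Mean event depth, mm.
#' @return Numeric vector of daily rainfall, mm.
#' @export
simulate_rainfall <- function(n_days, start_date, wet_window, rain_rate,
                              event_depth_mean) {
  dates <- start_date + 0:(n_days - 1L)
  doy <- as.POSIXlt(dates)$yday + 1L
  wet <- in_doy_window(doy, wet_window)
  rain <- numeric(n_days)
  n_ev <- stats::rpois(sum(wet), rain_rate)
  rain[wet] <- vapply(n_ev, function(k) {
    if (k == 0L) 0 else sum(stats::rexp(k, rate = 1 / event_depth_mean))
  }, numeric(1))
  rain
}

#' Generate a daily soil-moisture series with a bucket model
#'
#' Rainfall pulses ([simulate_rainfall()]) fill a single surface store that
#' loses a fixed fraction `sm_decay` of its content per day; the store is
#' expressed as volumetric % over a 300 mm layer and clamped to
#' \[0.1, `sm_field_capacity`\] so log transforms stay finite. The store
#' starts half full.
#'
#' @param config A [synth_config()].
#' @param site_latitude Latitude in degrees (selects wet-season timing).
#' @param n_days Series length (>= 1).
#' @param start_date First day (default 2008-01-01).
#' @return Numeric vector of volumetric soil moisture (%), with the daily
#'   rainfall (mm) attached as attribute `rain_mm`.
#' @export
generate_soil_moisture <- function(config, site_latitude, n_days,
                                   start_date = as.Date("2008-01-01")) {
  validate_synth_config(config)
  stopifnot(n_days >= 1)
  win <- shift_window_south(config$wet_season_doy, site_latitude)
  rain <- simulate_rainfall(n_days, start_date, win, config$rain_rate,
                            config$event_depth_mean)
  sm <- numeric(n_days)
  floor_sm <- max(.SM_EPS, config$sm_residual)
  s <- config$sm_field_capacity / 2
  for (d in seq_len(n_days)) {
    s <- s * (1 - config$sm_decay) + rain[d] / .SOIL_DEPTH_MM * 100
    s <- min(s, config$sm_field_capacity)
    s <- max(s, floor_sm)
    sm[d] <- s
  }
  attr(sm, "rain_mm") <- rain
  sm
}

#' Sample a daily series the way 16-day satellite composites do
#'
#' One observation per `composite_period`-day window; its acquisition date is
#' the window start plus a uniform integer offset in \[0, `jitter`\]. A
#' fraction `gap_fraction` of the composites is then removed at random
#' (rounded to a whole count). Only complete windows yield observations.
#'
#' @param dates Daily `Date` vector.
#' @param values Daily values, same length.
#' @param composite_period Window length in days (>= 1).
#' @param jitter Maximum offset in days, `0 <= jitter < composite_period`.
#' @param gap_fraction Fraction of observations dropped, in \[0, 1).
#' @return `data.frame` with columns `acq_date`, `ndvi`.
#' @export
composite_sample <- function(dates, values, composite_period = 16L,
                             jitter = 0L, gap_fraction = 0) {
  n <- length(values)
  if (n == 0L) stop("empty input series", call. = FALSE)
  stopifnot(length(dates) == n, composite_period >= 1L,
            jitter >= 0L, jitter < composite_period,
            gap_fraction >= 0, gap_fraction < 1)
  n_win <- n %/% composite_period
  if (n_win == 0L) stop("series shorter than one composite window", call. = FALSE)
  starts <- (seq_len(n_win) - 1L) * composite_period + 1L
  off <- if (jitter > 0L) sample.int(jitter + 1L, n_win, replace = TRUE) - 1L
         else integer(n_win)
  idx <- starts + off
  keep <- rep(TRUE, n_win)
  n_drop <- round(gap_fraction * n_win)
  if (n_drop > 0L) keep[sample.int(n_win, n_drop)] <- FALSE
  data.frame(acq_date = as.Date(dates[idx[keep]]), ndvi = values[idx[keep]])
}

# Leading-window rolling aggregate: out[d] = fun(x[d .. d+width-1]), NA
# where the window runs off the series end.
roll_agg <- function(x, width, fun) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (d in seq_len(n - width + 1L)) out[d] <- fun(x[d:(d + width - 1L)])
  out
}

# Evaluate one planted regression term on aggregated grid climate.
term_regressor <- function(term, sm, dayl, map) {
  x <- switch(term$transform,
              log = log(sm),
              log_map = log(sm * map),
              identity = if (term$variable == "dayl") dayl else
                stop("identity transform is reserved for dayl", call. = FALSE))
  if (term$variable == "sm" && term$transform == "identity") {
    stop("sm terms must use a log-family transform", call. = FALSE)
  }
  x
}

lag_vector <- function(x, lag) {
  n <- length(x)
  if (lag >= n) stop("lag longer than series", call. = FALSE)
  if (lag == 0L) x else c(rep(NA_real_, lag), x[seq_len(n - lag)])
}

#' Generate one synthetic savannah site
#'
#' Draws site metadata (latitude, MAP, tree cover, aridity index), simulates
#' daily soil moisture, computes day length, aggregates both onto the 8-day
#' analysis grid, plants the grid-level NDVI truth
#' `intercept + sum(coef * transform(driver lagged by lag steps))`, clips to
#' \[0, 1\], interpolates to a daily latent series, adds daily Gaussian
#' noise, and samples acquisitions with [composite_sample()].
#'
#' Because the truth is built from the same 8-day median/maximum aggregates
#' the model stage regresses on, a noise-free ensemble is an exact fixed
#' point of the selection pipeline.
#'
#' @param config A [synth_config()].
#' @param site_index Integer site number (seeds the per-site RNG stream).
#' @return A `site_record`: list with `site_id`, `latitude`, `map`,
#'   `tree_cover`, `aridity_index`, `climate` (daily date/sm_volpct/tair_c),
#'   `ndvi` (acq_date/ndvi), and `aligned` (grid truth: step_date,
#'   ndvi = truth + grid-level noise, ndvi_true, sm, dayl).
#' @export
generate_site <- function(config, site_index) {
  validate_synth_config(config)
  set.seed((config$seed %% 100000L) * 10007L + as.integer(site_index) * 7919L)

  latitude <- stats::runif(1, config$latitude_range[1], config$latitude_range[2])
  map <- stats::runif(1, config$map_range[1], config$map_range[2])
  tree_cover <- min(96, max(2, 100 * (map - 0.2) / 1.2 + stats::rnorm(1, 0, 8)))
  aridity_index <- map / 2   # nominal PET of 2 m/year

  start_date <- as.Date("2008-01-01")
  n_days <- config$n_years * 365L
  sm_daily <- generate_soil_moisture(config, latitude, n_days, start_date)
  dates <- start_date + 0:(n_days - 1L)
  doy <- as.POSIXlt(dates)$yday + 1L
  peak <- if (latitude >= 0) 196 else 15
  tair <- 22 + (abs(latitude) / 40) * 10 * cos(2 * pi * (doy - peak) / 365) +
    stats::rnorm(n_days, 0, 1)

  # full 8-day grid over the climate record
  n_steps <- n_days %/% 8L
  grid <- start_date + (seq_len(n_steps) - 1L) * 8L
  agg <- aggregate_climate(
    data.frame(date = dates, sm_volpct = as.numeric(sm_daily)),
    latitude, grid)

  lags <- vapply(config$true_terms, function(t) t$lag, integer(1))
  max_lag <- max(c(lags, 0L))
  ndvi_true <- rep(config$intercept, n_steps)
  for (tm in config$true_terms) {
    x <- term_regressor(tm, agg$sm, agg$dayl, map)
    ndvi_true <- ndvi_true + tm$coefficient * lag_vector(x, tm$lag)
  }
  keep <- (max_lag + 1L):n_steps
  grid <- grid[keep]
  ndvi_true <- pmin(1, pmax(0, ndvi_true[keep]))

  # grid-level noisy observation (model-stage input without preprocessing)
  ndvi_grid <- pmin(1, pmax(0, ndvi_true +
                              stats::rnorm(length(keep), 0, config$noise_sd)))

  # Daily latent NDVI: the same lagged functional, applied to rolling 8-day
  # leading-window aggregates of the daily climate. On any 8-day grid this
  # reduces exactly to the regression the model stage fits, so composite
  # acquisition jitter shifts the analysis grid without distorting the
  # planted response.
  roll_sm <- roll_agg(as.numeric(sm_daily), 8L, stats::median)
  roll_dl <- roll_agg(day_length(latitude, dates), 8L, max)
  day_ok <- (8L * max_lag + 1L):(n_days - 7L)
  latent <- rep(config$intercept, length(day_ok))
  for (tm in config$true_terms) {
    x <- term_regressor(tm, roll_sm, roll_dl, map)
    latent <- latent + tm$coefficient * x[day_ok - 8L * tm$lag]
  }
  day_span <- dates[day_ok]
  latent <- pmin(1, pmax(0, latent + stats::rnorm(length(latent), 0,
                                                  config$noise_sd)))
  ndvi_obs <- composite_sample(day_span, latent, config$composite_period,
                               config$jitter, config$gap_fraction)

  aligned <- aligned_series(
    data.frame(step_date = grid, ndvi = ndvi_grid, ndvi_true = ndvi_true,
               sm = agg$sm[keep], dayl = agg$dayl[keep]),
    site_id = sprintf("site%02d", site_index), latitude = latitude,
    map = map, tree_cover = tree_cover)

  structure(list(
    site_id = sprintf("site%02d", site_index),
    latitude = latitude, map = map, tree_cover = tree_cover,
    aridity_index = aridity_index,
    climate = data.frame(date = dates, sm_volpct = as.numeric(sm_daily),
                         tair_c = tair),
    ndvi = ndvi_obs,
    aligned = aligned), class = "site_record")
}

#' @export
print.site_record <- function(x, ...) {
  cat(sprintf(
    "<site_record> %s: lat %.2f, MAP %.2f m/yr, tree cover %.0f%%, %d climate days, %d NDVI acquisitions\n",
    x$site_id, x$latitude, x$map, x$tree_cover, nrow(x$climate), nrow(x$ndvi)))
  invisible(x)
}

#' Generate an ensemble of synthetic sites
#'
#' @param config A [synth_config()].
#' @return List of `site_record`s of length `config$n_sites`.
#' @export
generate_ensemble <- function(config) {
  lapply(seq_len(config$n_sites), function(i) generate_site(config, i))
}

#' Extract the aligned grid-truth tables from an ensemble
#'
#' Convenience accessor handing the model stages the generator's 8-day
#' aligned series (observation = truth + grid-level noise).
#'
#' @param sites List of `site_record`s.
#' @param noise_free If `TRUE`, substitute the noise-free truth for the
#'   `ndvi` column.
#' @return List of `aligned_series`.
#' @export
aligned_truth <- function(sites, noise_free = FALSE) {
  lapply(sites, function(s) {
    a <- s$aligned
    if (noise_free) a$ndvi <- a$ndvi_true
    a
  })
}
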