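# Preprocessing: from raw per-site series to the aligned 8-day analysis grid.

#' Astronomical day length from latitude and date
#'
#' Standard solar-geometry day length using the Cooper declination
#' approximation: declination \eqn{\delta = 23.44^\circ \sin(2\pi(284+doy)/365)},
#' hour angle \eqn{\omega = \arccos(-\tan\phi\,\tan\delta)} with the argument
#' clamped to \eqn{[-1, 1]} (polar day/night), day length \eqn{24\omega/\pi}.
#'
#' @param latitude Latitude in decimal degrees, in \[-90, 90\].
#' @param dates `Date` vector (or anything coercible with `as.Date()`).
#' @return Numeric vector of day lengths in hours, in \[0, 24\].
#' @examples
#' day_length(0, as.Date("2010-06-21"))    # ~12 h at the equator
#' day_length(80, as.Date("2010-06-21"))   # 24 h, polar day
#' @export
day_length <- function(latitude, dates) {
  if (any(latitude < -90 | latitude > 90)) {
    stop("`latitude` must lie in [-90, 90]", call. = FALSE)
  }
  dates <- as.Date(dates)
  doy <- as.POSIXlt(dates)$yday + 1L
  decl <- (23.44 * pi / 180) * sin(2 * pi * (284 + doy) / 365)
  cos_omega <- -tan(latitude * pi / 180) * tan(decl)
  cos_omega <- pmin(1, pmax(-1, cos_omega))
  24 * acos(cos_omega) / pi
}

#' Gap-fill an NDVI series and resample it onto a regular grid
#'
#' Linear interpolation between consecutive observations, evaluated on a
#' regular grid (default 8-day) running from the first to the last
#' acquisition date. No extrapolation beyond the observed span.
#'
#' @param dates Strictly increasing acquisition dates (`Date`).
#' @param values NDVI values, one per date.
#' @param step Grid spacing in days (default 8).
#' @return `data.frame` with columns `step_date` and `ndvi`.
#' @export
gapfill_resample <- function(dates, values, step = 8L) {
  dates <- as.Date(dates)
  n <- length(dates)
  if (n != length(values)) stop("`dates` and `values` lengths differ", call. = FALSE)
  if (n < 2L) stop("need at least 2 observations to interpolate", call. = FALSE)
  if (any(diff(as.numeric(dates)) <= 0)) {
    stop("acquisition dates must be strictly increasing", call. = FALSE)
  }
  grid <- seq(dates[1L], dates[n], by = step)
  out <- stats::approx(as.numeric(dates), values, xout = as.numeric(grid),
                       method = "linear", rule = 1)$y
  data.frame(step_date = grid, ndvi = out)
}

# Savitzky-Golay midpoint weights for a full window of half-width h.
sg_weights <- function(h, degree) {
  x <- (-h):h
  X <- outer(x, 0:degree, `^`)
  # first row of (X'X)^{-1} X' gives the fitted value at the window centre
  solve(crossprod(X), t(X))[1L, ]
}

# Least-squares polynomial fit over a (possibly truncated) window, evaluated
# at position i. Degree is reduced if the window holds too few points.
sg_fit_point <- function(x, i, h, degree) {
  idx <- max(1L, i - h):min(length(x), i + h)
  t0 <- idx - i
  deg <- min(degree, length(idx) - 1L)
  X <- outer(t0, 0:deg, `^`)
  beta <- qr.coef(qr(X), x[idx])
  beta[1L]
}

#' Adaptive Savitzky-Golay smoothing with a jump rule
#'
#' Each point is replaced by the centre value of a least-squares polynomial
#' (default degree 2) fitted over a moving window (default 7 steps). Points
#' whose raw value differs from either temporal neighbour by more than
#' `jump_threshold` are instead fitted over `small_window` steps, so genuine
#' rapid transitions (savannah green-up) are not smoothed away. Edges use the
#' same polynomial fitted on the truncated window and evaluated at the edge
#' point, which preserves exact reproduction of polynomials up to `degree`.
#'
#' @param x Numeric series on a regular grid.
#' @param window Odd full window width for the main fit (default 7).
#' @param degree Polynomial degree (default 2).
#' @param jump_threshold Raw-series neighbour difference above which the
#'   small window is used (default 0.08, dimensionless NDVI units).
#' @param small_window Odd window used at detected jumps (default 3).
#' @return Smoothed numeric series, same length as `x`.
#' @export
adaptive_savgol <- function(x, window = 7L, degree = 2L,
                            jump_threshold = 0.08, small_window = 3L) {
  if (window %% 2L == 0L || small_window %% 2L == 0L) {
    stop("`window` and `small_window` must be odd", call. = FALSE)
  }
  n <- length(x)
  if (n < window) stop("series shorter than `window`", call. = FALSE)
  if (anyNA(x)) stop("series contains missing values", call. = FALSE)
  h <- (window - 1L) %/% 2L

  out <- numeric(n)
  w <- sg_weights(h, degree)
  # interior points by convolution, edges by truncated-window fits
  if (n >= window) {
    emb <- stats::embed(x, window)      # row i = x[(i+window-1):i]
    out[(h + 1L):(n - h)] <- as.numeric(emb %*% rev(w))
  }
  for (i in seq_len(h)) {
    out[i] <- sg_fit_point(x, i, h, degree)
    out[n - i + 1L] <- sg_fit_point(x, n - i + 1L, h, degree)
  }

  # jump detection on the RAW series, against either temporal neighbour
  dprev <- c(0, abs(diff(x)))          # |x_i - x_{i-1}|, 0 for the first point
  dnext <- c(abs(diff(x)), 0)          # |x_i - x_{i+1}|, 0 for the last point
  jump <- dprev > jump_threshold | dnext > jump_threshold
  if (any(jump)) {
    hs <- (small_window - 1L) %/% 2L
    for (i in which(jump)) out[i] <- sg_fit_point(x, i, hs, degree)
  }
  out
}

#' Aggregate daily climate onto the NDVI grid
#'
#' For each grid step, the 8-day median of daily soil moisture and the
#' maximum daily day length over the half-open window
#' \[step_date, step_date + step). A partial final window is allowed; a
#' window containing no daily values is an error.
#'
#' @param climate `data.frame` with columns `date` and `sm_volpct`
#'   (volumetric soil moisture, %).
#' @param latitude Site latitude in degrees (for day length).
#' @param grid_dates `Date` vector of grid step dates.
#' @param step Window width in days (default 8).
#' @return `data.frame` with columns `step_date`, `sm` (median volumetric %),
#'   `dayl` (maximum hours).
#' @export
aggregate_climate <- function(climate, latitude, grid_dates, step = 8L) {
  stopifnot(all(c("date", "sm_volpct") %in% names(climate)))
  d <- as.numeric(as.Date(climate$date))
  g <- as.numeric(as.Date(grid_dates))
  dl_daily <- day_length(latitude, climate$date)
  sm <- numeric(length(g))
  dayl <- numeric(length(g))
  for (k in seq_along(g)) {
    sel <- d >= g[k] & d < g[k] + step
    if (!any(sel)) {
      stop(sprintf("no daily climate values in window starting %s",
                   as.Date(grid_dates[k])), call. = FALSE)
    }
    sm[k] <- stats::median(climate$sm_volpct[sel])
    dayl[k] <- max(dl_daily[sel])
  }
  data.frame(step_date = as.Date(grid_dates), sm = sm, dayl = dayl)
}

#' Screen candidate explanatory variables for mutual collinearity
#'
#' Computes each candidate's Pearson correlation with NDVI per site and
#' averages across sites. Any candidate pair whose mean mutual absolute
#' correlation exceeds `threshold` loses its member with the lower mean
#' absolute NDVI correlation (dropped iteratively, worst pair first). A
#' constant series makes the correlation undefined; such variables are
#' dropped with a warning.
#'
#' @param tables List of per-site `data.frame`s, each holding a `ndvi`
#'   column plus the candidate columns.
#' @param candidates Character vector of candidate column names; default all
#'   shared columns except `ndvi` and `step_date`.
#' @param threshold Mean mutual |r| above which a pair is considered
#'   collinear (default 0.7).
#' @return List with `retained` (character), `dropped` (character),
#'   `ndvi_correlation` (named mean r with NDVI) and `mutual` (mean |r|
#'   matrix between candidates).
#' @export
screen_variables <- function(tables, candidates = NULL, threshold = 0.7) {
  stopifnot(length(tables) >= 1L)
  nm <- Reduce(intersect, lapply(tables, names))
  if (is.null(candidates)) candidates <- setdiff(nm, c("ndvi", "ndvi_true", "step_date"))
  if (!all(candidates %in% nm)) {
    stop("candidate columns missing from some site tables", call. = FALSE)
  }
  m <- length(candidates)
  r_ndvi <- matrix(NA_real_, length(tables), m, dimnames = list(NULL, candidates))
  mutual <- array(NA_real_, c(length(tables), m, m))
  for (s in seq_along(tables)) {
    tb <- tables[[s]]
    for (j in seq_len(m)) {
      vj <- tb[[candidates[j]]]
      if (stats::sd(vj) > 0 && stats::sd(tb$ndvi) > 0) {
        r_ndvi[s, j] <- stats::cor(vj, tb$ndvi)
      }
      for (k in seq_len(m)) {
        vk <- tb[[candidates[k]]]
        if (stats::sd(vj) > 0 && stats::sd(vk) > 0) {
          mutual[s, j, k] <- abs(stats::cor(vj, vk))
        }
      }
    }
  }
  mean_r <- colMeans(r_ndvi)
  mean_mutual <- apply(mutual, c(2, 3), mean)
  dimnames(mean_mutual) <- list(candidates, candidates)

  dropped <- character(0)
  bad <- candidates[is.na(mean_r)]
  if (length(bad)) {
    warning("dropping variable(s) with undefined NDVI correlation (constant series): ",
            paste(bad, collapse = ", "), call. = FALSE)
    dropped <- bad
  }
  retained <- setdiff(candidates, dropped)
  repeat {
    if (length(retained) < 2L) break
    sub <- mean_mutual[retained, retained, drop = FALSE]
    diag(sub) <- 0
    if (max(sub, na.rm = TRUE) <= threshold) break
    ij <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    pair <- retained[ij]
    loser <- pair[which.min(abs(mean_r[pair]))]
    dropped <- c(dropped, loser)
    retained <- setdiff(retained, loser)
  }
  list(retained = retained, dropped = dropped,
       ndvi_correlation = mean_r, mutual = mean_mutual)
}

#' Align one site onto the 8-day analysis grid
#'
#' Runs the full preprocessing chain for one site: gap-fill + resample the
#' NDVI acquisitions onto an 8-day grid anchored at the first acquisition
#' date, smooth with [adaptive_savgol()], and aggregate the daily climate
#' (8-day median soil moisture, maximum day length) onto the same grid.
#'
#' @param site A `site_record` (see [generate_site()] or [read_sites()]).
#' @param window,degree,jump_threshold,small_window Passed to
#'   [adaptive_savgol()].
#' @param step Grid spacing in days (default 8).
#' @return An `aligned_series`: `data.frame` with columns `step_date`,
#'   `ndvi` (smoothed), `sm`, `dayl`, carrying attributes `site_id`,
#'   `latitude`, `map`, `tree_cover`.
#' @export
align_site <- function(site, window = 7L, degree = 2L, jump_threshold = 0.08,
                       small_window = 3L, step = 8L) {
  gf <- gapfill_resample(site$ndvi$acq_date, site$ndvi$ndvi, step = step)
  agg <- aggregate_climate(site$climate, site$latitude, gf$step_date, step = step)
  sm_raw <- gf$ndvi
  out <- data.frame(step_date = gf$step_date,
                    ndvi = adaptive_savgol(sm_raw, window = window, degree = degree,
                                           jump_threshold = jump_threshold,
                                           small_window = small_window),
                    sm = agg$sm, dayl = agg$dayl)
  aligned_series(out, site_id = site$site_id, latitude = site$latitude,
                 map = site$map, tree_cover = site$tree_cover)
}

#' Construct an aligned series object
#'
#' Light S3 wrapper tying the per-site metadata the model stages need
#' (site id, latitude, MAP, tree cover) to the 8-day grid table.
#'
#' @param df `data.frame` with at least `step_date`, `ndvi`, `sm`, `dayl`.
#' @param site_id,latitude,map,tree_cover Site metadata; `map` in m/year.
#' @return The `data.frame` with class `aligned_series` and metadata attributes.
#' @export
aligned_series <- function(df, site_id, latitude = NA_real_, map = NA_real_,
                           tree_cover = NA_real_) {
  stopifnot(all(c("step_date", "ndvi", "sm", "dayl") %in% names(df)))
  structure(df, class = c("aligned_series", "data.frame"),
            site_id = site_id, latitude = latitude, map = map,
            tree_cover = tree_cover)
}

#' @export
print.aligned_series <- function(x, ...) {
  cat(sprintf("<aligned_series> site %s: %d steps of 8 days, MAP %.3g m/yr\n",
              attr(x, "site_id"), nrow(x), attr(x, "map")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}
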