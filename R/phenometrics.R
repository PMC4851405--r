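# Start-of-season and amplitude phenometrics on the 8-day grid.

# Interior local extrema with plateau handling: a plateau's first index is
# reported. Returns list(peaks, mins), both 1-based.
local_extrema <- function(x) {
  n <- length(x)
  peaks <- integer(0)
  mins <- integer(0)
  last_dir <- 0L
  run_end <- 1L
  for (i in 2:n) {
    d <- x[i] - x[i - 1L]
    dir <- sign(d)
    if (dir != 0L) {
      if (last_dir > 0L && dir < 0L) peaks <- c(peaks, run_end)
      if (last_dir < 0L && dir > 0L) mins <- c(mins, run_end)
      last_dir <- as.integer(dir)
      run_end <- i
    }
  }
  list(peaks = peaks, mins = mins)
}

#' Start-of-season indices of a smoothed NDVI series
#'
#' Growing cycles are delimited by local minima (the series start acts as
#' the first delimiter). A cycle's peak qualifies if its rise above the
#' preceding minimum is at least `min_prominence_frac` of the site
#' amplitude (max - min of the whole series). Within each qualifying
#' cycle, SOS is the index on the rising limb whose value is nearest to the
#' midpoint `(peak + preceding minimum) / 2`; ties go to the earlier index.
#'
#' @param x Smoothed NDVI series (length >= 5).
#' @param min_prominence_frac Minimum peak rise as a fraction of site
#'   amplitude (default 0.35).
#' @return Integer vector of SOS indices (1-based; possibly empty), with
#'   attributes `peaks` and `mins` (the matched cycle peak and preceding
#'   minimum per SOS) and `amplitude`.
#' @export
start_of_season <- function(x, min_prominence_frac = 0.35) {
  n <- length(x)
  if (n < 5L) stop("series too short for phenometrics (need >= 5)", call. = FALSE)
  if (anyNA(x)) stop("series contains missing values", call. = FALSE)
  amp <- max(x) - min(x)
  empty <- structure(integer(0), peaks = integer(0), mins = integer(0),
                     amplitude = amp)
  if (amp <= 0) return(empty)
  ex <- local_extrema(x)
  if (length(ex$peaks) == 0L) return(empty)
  delim <- sort(unique(c(1L, ex$mins)))
  sos <- integer(0); pk <- integer(0); mn <- integer(0)
  for (p in ex$peaks) {
    m <- max(delim[delim < p])
    if (x[p] - x[m] < min_prominence_frac * amp) next
    mid <- (x[p] + x[m]) / 2
    limb <- m:p
    s <- limb[which.min(abs(x[limb] - mid))]
    sos <- c(sos, s); pk <- c(pk, p); mn <- c(mn, m)
  }
  structure(sos, peaks = pk, mins = mn, amplitude = amp)
}

#' Series amplitude
#'
#' Maximum minus minimum of the series (per whole site record).
#'
#' @param x Numeric series.
#' @return Non-negative scalar.
#' @export
amplitude <- function(x) max(x) - min(x)

#' Compare phenometrics between a modelled and an observed series
#'
#' Cycles are matched greedily by nearest peak index (one-to-one, closest
#' pairs first); unmatched cycles are counted, not an error. The modelled
#' series is expected to have been smoothed the same way as the observed
#' one before this call (see [adaptive_savgol()]).
#'
#' @param model Modelled NDVI series (numeric, same grid as `observed`).
#' @param observed Observed NDVI series.
#' @param min_prominence_frac Passed to [start_of_season()].
#' @return List with `sos_error` (model SOS - observed SOS per matched
#'   cycle, 8-day steps), `amplitude_error` (model - observed),
#'   `n_matched`, `n_model_cycles`, `n_observed_cycles`.
#' @export
compare_phenometrics <- function(model, observed, min_prominence_frac = 0.35) {
  if (length(model) != length(observed)) {
    stop("series must share one grid", call. = FALSE)
  }
  sm <- start_of_season(model, min_prominence_frac)
  so <- start_of_season(observed, min_prominence_frac)
  pm <- attr(sm, "peaks"); po <- attr(so, "peaks")
  n_m <- length(pm); n_o <- length(po)
  err <- numeric(0)
  if (n_m > 0L && n_o > 0L) {
    pairs <- expand.grid(i = seq_len(n_o), j = seq_len(n_m))
    pairs$d <- abs(po[pairs$i] - pm[pairs$j])
    pairs <- pairs[order(pairs$d), , drop = FALSE]
    used_i <- logical(n_o); used_j <- logical(n_m)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$i[r]; j <- pairs$j[r]
      if (!used_i[i] && !used_j[j]) {
        used_i[i] <- TRUE; used_j[j] <- TRUE
        err <- c(err, as.numeric(sm[j]) - as.numeric(so[i]))
      }
    }
  }
  if (n_m != n_o) {
    message(sprintf("cycle-count mismatch: %d model vs %d observed; matched %d",
                    n_m, n_o, length(err)))
  }
  list(sos_error = err,
       amplitude_error = amplitude(model) - amplitude(observed),
       n_matched = length(err), n_model_cycles = n_m, n_observed_cycles = n_o)
}
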