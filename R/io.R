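# Interface: CSV I/O, pipeline configuration, the end-to-end run, and a CLI.

#' Pipeline configuration with the study defaults
#'
#' @param input_dir,output_dir Paths (only `output_dir` is required by
#'   [run_pipeline()] when simulating).
#' @param window,small_window,jump_threshold Smoothing knobs (defaults 7, 3,
#'   0.08).
#' @param max_lag Model-search lag bound in 8-day steps (default 10).
#' @param reps,n_test Evaluation knobs (defaults 1000 and 3).
#' @param seed Integer seed driving every stochastic stage.
#' @param synth A [synth_config()] used when simulating input.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = NULL,
                            window = 7L, small_window = 3L,
                            jump_threshold = 0.08, max_lag = 10L,
                            reps = 1000L, n_test = 3L, seed = 42L,
                            synth = synth_config(seed = seed)) {
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 window = as.integer(window),
                 small_window = as.integer(small_window),
                 jump_threshold = jump_threshold,
                 max_lag = as.integer(max_lag), reps = as.integer(reps),
                 n_test = as.integer(n_test), seed = as.integer(seed),
                 synth = synth),
            class = "pipeline_config")
}

#' Write a synthetic ensemble as plain CSV files
#'
#' Layout: `metadata.csv` (site_id, latitude, map_m_per_yr, tree_cover_pct,
#' aridity_index), `climate/<site_id>.csv` (date, sm_volpct, tair_c) and
#' `ndvi/<site_id>.csv` (acq_date, ndvi).
#'
#' @param sites List of `site_record`s.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(sites, dir) {
  dir.create(file.path(dir, "climate"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "ndvi"), showWarnings = FALSE)
  meta <- do.call(rbind, lapply(sites, function(s) {
    data.frame(site_id = s$site_id, latitude = s$latitude,
               map_m_per_yr = s$map, tree_cover_pct = s$tree_cover,
               aridity_index = s$aridity_index)
  }))
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  for (s in sites) {
    utils::write.csv(s$climate, file.path(dir, "climate", paste0(s$site_id, ".csv")),
                     row.names = FALSE)
    utils::write.csv(s$ndvi, file.path(dir, "ndvi", paste0(s$site_id, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

read_csv_checked <- function(path, what, site_id) {
  if (!file.exists(path)) {
    stop(sprintf("site %s: missing %s file %s", site_id, what, path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    stop(sprintf("site %s: empty %s file", site_id, what), call. = FALSE)
  }
  df
}

parse_date_col <- function(x, site_id, what) {
  d <- as.Date(x)
  if (anyNA(d)) {
    stop(sprintf("site %s: unparsable date in %s series", site_id, what),
         call. = FALSE)
  }
  d
}

#' Read site records from the CSV layout written by [write_ensemble()]
#'
#' Validates schema, date parsing, monotone daily climate dates, and unit
#' sanity: MAP must be < 10 m/year (a value like 500 indicates mm/year) and
#' soil moisture must lie in (0, 100\] volumetric %.
#'
#' @param metadata_csv Path to `metadata.csv`.
#' @param climate_dir,ndvi_dir Per-site series directories; default
#'   `climate/` and `ndvi/` beside the metadata file.
#' @return List of `site_record`s.
#' @export
read_sites <- function(metadata_csv,
                       climate_dir = file.path(dirname(metadata_csv), "climate"),
                       ndvi_dir = file.path(dirname(metadata_csv), "ndvi")) {
  meta <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE)
  req <- c("site_id", "latitude", "map_m_per_yr", "tree_cover_pct", "aridity_index")
  if (!all(req %in% names(meta))) {
    stop("metadata is missing columns: ",
         paste(setdiff(req, names(meta)), collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$site_id[i]
    if (meta$map_m_per_yr[i] >= 10) {
      stop(sprintf("site %s: MAP %.3g m/yr fails unit sanity (< 10); is it mm/yr?",
                   id, meta$map_m_per_yr[i]), call. = FALSE)
    }
    clim <- read_csv_checked(file.path(climate_dir, paste0(id, ".csv")),
                             "climate", id)
    clim$date <- parse_date_col(clim$date, id, "climate")
    if (any(diff(as.numeric(clim$date)) != 1)) {
      stop(sprintf("site %s: climate dates must be strictly increasing and daily", id),
           call. = FALSE)
    }
    if (any(clim$sm_volpct <= 0 | clim$sm_volpct > 100)) {
      stop(sprintf("site %s: soil moisture outside (0, 100] volumetric %%", id),
           call. = FALSE)
    }
    nd <- read_csv_checked(file.path(ndvi_dir, paste0(id, ".csv")), "ndvi", id)
    nd$acq_date <- parse_date_col(nd$acq_date, id, "ndvi")
    if (any(diff(as.numeric(nd$acq_date)) <= 0)) {
      stop(sprintf("site %s: NDVI acquisition dates must be strictly increasing", id),
           call. = FALSE)
    }
    if (any(nd$ndvi < -1 | nd$ndvi > 1)) {
      stop(sprintf("site %s: NDVI outside [-1, 1]", id), call. = FALSE)
    }
    structure(list(site_id = id, latitude = meta$latitude[i],
                   map = meta$map_m_per_yr[i],
                   tree_cover = meta$tree_cover_pct[i],
                   aridity_index = meta$aridity_index[i],
                   climate = clim, ndvi = nd), class = "site_record")
  })
}

model_to_list <- function(model) {
  list(terms = lapply(model$terms, function(t) {
    list(variable = t$variable, transform = t$transform, lag = t$lag)
  }),
  coefficients = as.list(model$coefficients),
  intercept = model$intercept, rss = model$rss, r2 = model$r2,
  bic = model$bic, n_obs = model$n_obs)
}

write_model_json <- function(model, path, ranking_top = 20L) {
  obj <- model_to_list(model)
  if (!is.null(model$ranking)) {
    obj$ranking <- utils::head(model$ranking, ranking_top)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model artifact written by [run_pipeline()]
#'
#' @param path Path to `model.json`.
#' @return A `candidate_model` (without ranking).
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  terms <- lapply(obj$terms, function(t) {
    term_spec(t$variable, t$transform, t$lag)
  })
  structure(list(terms = terms,
                 coefficients = stats::setNames(
                   vapply(obj$coefficients, as.numeric, numeric(1)),
                   vapply(terms, format, character(1))),
                 intercept = as.numeric(obj$intercept),
                 rss = as.numeric(obj$rss), r2 = as.numeric(obj$r2),
                 bic = as.numeric(obj$bic), n_obs = as.integer(obj$n_obs)),
            class = "candidate_model")
}

log_stage <- function(log_path, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(line)
  cat(line, "\n", file = log_path, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate (or read) site records, align every site onto
#' the 8-day grid, exhaustive BIC model selection, per-site importance
#' decomposition, holdout cross-validation + site-count sensitivity +
#' phenometric errors. All artifacts are plain text under `out_dir`:
#' `aligned/<site>.csv`, `model.json`, `importance.csv`,
#' `eval_summary.csv`, `per_site_metrics.csv`, `sensitivity.csv`, `run.log`.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config A [pipeline_config()] with `output_dir` set.
#' @param simulate If `TRUE` (default) generate the ensemble from
#'   `config$synth`; otherwise read it from `config$input_dir`.
#' @return List with `model`, `importance`, `evaluation`, `sensitivity`,
#'   `phenometrics`, and the artifact directory.
#' @export
run_pipeline <- function(config, simulate = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  if (is.null(out)) stop("config$output_dir is required", call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "run.log")
  cat("", file = logf)
  log_stage(logf, "pipeline start: seed=%d max_lag=%d reps=%d n_test=%d",
            config$seed, config$max_lag, config$reps, config$n_test)

  if (simulate) {
    log_stage(logf, "simulate: %d sites x %d years (noise_sd=%.3g)",
              config$synth$n_sites, config$synth$n_years, config$synth$noise_sd)
    sites_raw <- generate_ensemble(config$synth)
    write_ensemble(sites_raw, file.path(out, "input"))
  } else {
    if (is.null(config$input_dir) || !dir.exists(config$input_dir)) {
      stop("input directory missing: ", config$input_dir %||% "<unset>",
           call. = FALSE)
    }
    log_stage(logf, "read: %s", config$input_dir)
    sites_raw <- read_sites(file.path(config$input_dir, "metadata.csv"))
  }

  log_stage(logf, "preprocess: window=%d small=%d jump=%.3g",
            config$window, config$small_window, config$jump_threshold)
  aligned <- lapply(sites_raw, function(s) {
    tryCatch(align_site(s, window = config$window,
                        jump_threshold = config$jump_threshold,
                        small_window = config$small_window),
             error = function(e) stop(sprintf("stage preprocess, site %s: %s",
                                              s$site_id, conditionMessage(e)),
                                      call. = FALSE))
  })
  dir.create(file.path(out, "aligned"), showWarnings = FALSE)
  for (a in aligned) {
    utils::write.csv(
      data.frame(step_date = a$step_date, ndvi_smooth = a$ndvi,
                 sm_med = a$sm, dayl_max = a$dayl),
      file.path(out, "aligned", paste0(attr(a, "site_id"), ".csv")),
      row.names = FALSE)
  }

  log_stage(logf, "select: exhaustive BIC search, max_lag=%d", config$max_lag)
  model <- select_model(aligned, max_lag = config$max_lag)
  write_model_json(model, file.path(out, "model.json"))
  log_stage(logf, "selected: NDVI = %s + %.4g (r2=%.3f, BIC=%.1f)",
            paste(sprintf("%.4g*%s", model$coefficients,
                          vapply(model$terms, format, character(1))),
                  collapse = " + "),
            model$intercept, model$r2, model$bic)

  log_stage(logf, "importance: grouped decomposition, lags 0..%d", config$max_lag)
  imp <- do.call(rbind, lapply(aligned, function(a) {
    r <- group_lmg(a, max_lag = config$max_lag)
    data.frame(site_id = r$site_id, sm_importance_pct = r$sm_importance,
               dayl_importance_pct = r$dayl_importance, total_r2 = r$total_r2)
  }))
  utils::write.csv(imp, file.path(out, "importance.csv"), row.names = FALSE)

  log_stage(logf, "evaluate: holdout %d/%d x %d reps",
            length(aligned) - config$n_test, config$n_test, config$reps)
  ev <- holdout_cv(aligned, model, n_test = config$n_test,
                   reps = config$reps, seed = config$seed)
  utils::write.csv(ev$reps, file.path(out, "eval_summary.csv"), row.names = FALSE)
  sens <- site_sensitivity(aligned, model, reps = config$reps,
                           seed = config$seed + 1L)
  utils::write.csv(sens, file.path(out, "sensitivity.csv"), row.names = FALSE)
  ph <- phenometric_errors(aligned, model, window = config$window,
                           jump_threshold = config$jump_threshold,
                           small_window = config$small_window)
  per_site <- merge(ev$per_site, ph, by = "site_id")
  utils::write.csv(per_site, file.path(out, "per_site_metrics.csv"),
                   row.names = FALSE)
  log_stage(logf,
            "done: RMSE %.3f +/- %.3f, r2 %.2f +/- %.2f, VIF %.2f, mean SOS err %.2f steps",
            ev$rmse_mean, ev$rmse_sd, ev$r2_mean, ev$r2_sd, ev$vif_mean,
            mean(ph$sos_error_steps, na.rm = TRUE))

  list(model = model, importance = imp, evaluation = ev, sensitivity = sens,
       phenometrics = per_site, dir = out)
}
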