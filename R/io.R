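# On-disk formats: two-column time-series TSV, BIDS-style events TSV and
# JSON parameter files. TSVs are tab-separated with a header row, '.'
# decimal and 12 significant digits (lossless round trips at double
# precision for the quantities handled here).

fmt_num <- function(v) formatC(v, digits = 12, format = "g")

#' Write / read a time series as two-column TSV
#'
#' Columns `time_s` and `value`; the reader checks grid uniformity.
#'
#' @param ts a [time_series()].
#' @param path file path.
#' @return `write_timeseries_tsv` returns `path` invisibly;
#'   `read_timeseries_tsv` returns a [time_series()].
#' @export
write_timeseries_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "ipc_ts"))
  df <- data.frame(time_s = fmt_num(ts_time(ts)), value = fmt_num(ts$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("time_s", "value") %in% names(df)))
    stop("time-series TSV needs columns 'time_s' and 'value'", call. = FALSE)
  tt <- suppressWarnings(as.numeric(df$time_s))
  vv <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(tt) | is.na(vv))
  if (length(bad))
    stop(sprintf("non-numeric cell in '%s' at line %d", path, bad[1] + 1L),
         call. = FALSE)
  dt <- check_uniform_grid(tt)
  time_series(vv, dt = dt, t0 = tt[1])
}

#' Write / read a trial schedule as BIDS-style events TSV
#'
#' Columns `onset` (s, within run), `duration` (s), `trial_type` and `run`.
#'
#' @param paradigm a [generate_paradigm()] design.
#' @param path file path.
#' @param duration stimulus duration written per trial (s).
#' @return `write_events_tsv` returns `path` invisibly; `read_events_tsv`
#'   returns a data.frame (`run`, `onset_s`, `condition`, `duration_s`).
#' @export
write_events_tsv <- function(paradigm, path, duration = 2.5) {
  stopifnot(inherits(paradigm, "paradigm"))
  df <- data.frame(onset = fmt_num(paradigm$onsets$onset_s),
                   duration = fmt_num(rep(duration,
                                          nrow(paradigm$onsets))),
                   trial_type = paradigm$onsets$condition,
                   run = paradigm$onsets$run)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("onset", "duration", "trial_type", "run")
  if (!all(need %in% names(df)))
    stop("events TSV needs columns onset, duration, trial_type, run",
         call. = FALSE)
  onset <- suppressWarnings(as.numeric(df$onset))
  dur <- suppressWarnings(as.numeric(df$duration))
  run <- suppressWarnings(as.integer(df$run))
  bad <- which(is.na(onset) | is.na(dur) | is.na(run))
  if (length(bad))
    stop(sprintf("non-numeric cell in '%s' at line %d", path, bad[1] + 1L),
         call. = FALSE)
  data.frame(run = run, onset_s = onset, condition = df$trial_type,
             duration_s = dur)
}

#' Serialize model parameters to JSON
#'
#' Flat JSON objects for [hrf_params()], [ipc_params()],
#' [two_state_params()] and [noise_model()]; the class is recorded in a
#' `.class` field so [read_params_json()] can rebuild the object through
#' its validating constructor.
#'
#' @param x a parameter object.
#' @param path file path.
#' @return `write_params_json` returns `path` invisibly;
#'   `read_params_json` returns the reconstructed object.
#' @export
write_params_json <- function(x, path) {
  cls <- class(x)[1]
  if (!cls %in% c("hrf_params", "ipc_params", "two_state_params",
                  "noise_model"))
    stop("unsupported parameter class: ", cls, call. = FALSE)
  lst <- unclass(x)
  lst$t_const <- NULL  # derived, not stored
  lst$.class <- cls
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- lst$.class
  lst$.class <- NULL
  lst <- lst[!vapply(lst, is.null, TRUE)]
  ctor <- switch(cls,
                 hrf_params = hrf_params,
                 ipc_params = ipc_params,
                 two_state_params = two_state_params,
                 noise_model = noise_model,
                 stop("unknown parameter class in '", path, "'",
                      call. = FALSE))
  do.call(ctor, lst)
}

check_config <- function(config, required) {
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Simulate a synthetic dataset to disk
#'
#' Generates a design and one synthetic subject, writing BIDS-style events,
#' the sampled BOLD, the ground-truth parameters and a manifest listing all
#' artifacts. Fully deterministic for a given `seed`.
#'
#' @param config list with fields `out_dir` (required), `seed` (required)
#'   and optionally `paradigm` (arguments for [generate_paradigm()]),
#'   `truth` (arguments for [ground_truth()]), `noise_sigma` (shortcut for
#'   white noise of that SD).
#' @return invisibly, the manifest list (paths written).
#' @export
run_simulate <- function(config) {
  check_config(config, c("out_dir", "seed"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  par_args <- config$paradigm %||% list()
  par_args$seed <- config$seed
  paradigm <- do.call(generate_paradigm, par_args)
  truth_args <- config$truth %||% list()
  if (!is.null(config$noise_sigma))
    truth_args$noise <- noise_model("white", sigma = config$noise_sigma,
                                    seed = config$seed + 1L)
  truth <- do.call(ground_truth, truth_args)
  subj <- generate_subject(paradigm, truth)

  paths <- list(
    events = file.path(config$out_dir, "events.tsv"),
    bold = file.path(config$out_dir, "bold.tsv"),
    truth_ipc = file.path(config$out_dir, "truth_ipc.json"),
    truth_hrf = file.path(config$out_dir, "truth_hrf.json"),
    manifest = file.path(config$out_dir, "manifest.json"))
  write_events_tsv(paradigm, paths$events)
  write_timeseries_tsv(subj$bold, paths$bold)
  write_params_json(truth$ipc, paths$truth_ipc)
  write_params_json(truth$hrf, paths$truth_hrf)
  manifest <- list(command = "simulate", seed = config$seed,
                   tr = paradigm$tr,
                   alpha = as.list(truth$alpha),
                   files = paths[c("events", "bold", "truth_ipc",
                                   "truth_hrf")])
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a dataset from disk
#'
#' Reads a sampled BOLD TSV and an events TSV, trial-averages the requested
#' conditions, runs the inversion (deconvolution, spline upsampling,
#' two-state fit, BOLD prediction) for each condition with a shared decay
#' rate, and writes fitted parameters plus a markdown report.
#'
#' @param config list with fields `bold`, `events`, `out_dir` (required)
#'   and optionally `hrf` (path to an HRF JSON; default canonical shapes),
#'   `conditions` (default `c("C", "IC")`), `paradigm` (design arguments
#'   matching the events file), `window_s` (default 15), `reference`
#'   (condition normalizing the capacities, default `"C"`).
#' @return invisibly, a list with the per-condition `fit_result`s and the
#'   capacity report.
#' @export
run_fit <- function(config) {
  check_config(config, c("bold", "events", "out_dir"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  bold <- read_timeseries_tsv(config$bold)
  events <- read_events_tsv(config$events)
  conditions <- config$conditions %||% c("C", "IC")
  window_s <- config$window_s %||% 15
  reference <- config$reference %||% conditions[1]
  hrf <- if (!is.null(config$hrf)) read_params_json(config$hrf)
         else hrf_params()

  n_runs <- max(events$run)
  volumes_per_run <- length(bold$values) %/% n_runs
  paradigm <- structure(
    list(n_runs = n_runs, volumes_per_run = volumes_per_run, tr = bold$dt,
         baseline_s = NA_real_, trials_per_condition = NA_integer_,
         conditions = unique(events$condition), mode = "from_file",
         run_duration_s = volumes_per_run * bold$dt, seed = NA_integer_,
         onsets = events[, c("run", "onset_s", "condition")]),
    class = "paradigm")

  irfs <- lapply(conditions, function(cond)
    trial_average(bold, paradigm, cond, window_s = window_s))
  names(irfs) <- conditions

  cfg <- deconv_config()
  x_fine <- lapply(irfs, function(y)
    spline_upsample(deconvolve_ls(y, hrf, cfg), fine_dt = cfg$fine_dt))
  fits <- fit_two_state_shared(x_fine, y_list = irfs, hrf = hrf)
  frs <- lapply(conditions, function(cond)
    predict_and_score(fits[[cond]], hrf, irfs[[cond]]))
  names(frs) <- conditions

  report <- capacity_table(fits, reference = reference, hrf = hrf)
  for (cond in conditions) {
    out <- list(condition = cond,
                params = unclass(fits[[cond]]),
                mse = frs[[cond]]$mse,
                derived = unclass(derive_capacities(
                  fits[[cond]], reference_amp = fits[[reference]]$a,
                  hrf = hrf)))
    jsonlite::write_json(out,
                         file.path(config$out_dir,
                                   sprintf("fit_%s.json", cond)),
                         auto_unbox = TRUE, digits = NA, null = "null")
    write_timeseries_tsv(frs[[cond]]$y_pred,
                         file.path(config$out_dir,
                                   sprintf("pred_%s.tsv", cond)))
  }
  writeLines(report_markdown(report),
             file.path(config$out_dir, "report.md"))
  invisible(list(fits = frs, report = report))
}
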