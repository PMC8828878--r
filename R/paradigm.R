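#' Flanker-style rapid event-related design
#'
#' Generates a randomized trial schedule emulating the flanker selective-
#' attention experiment: `n_runs` runs of `volumes_per_run` volumes at
#' `tr` seconds, each run opening with a fixation baseline, followed by
#' trials of the Congruent (`C`), Incongruent (`IC`) and Neutral (`N`)
#' conditions presented in random order at onsets that are multiples of the
#' TR. With the defaults (4 runs x 164 volumes x TR 2.5 s, 32 trials per
#' condition per run = 384 trials) the mean onset-to-onset interval, total
#' acquisition time divided by trial count, is 4.27 s.
#'
#' `mode = "isolated"` enforces a minimum onset-to-onset spacing
#' (`min_isi_s`, default 20 s) so that single-trial responses do not
#' overlap; this requires a sparser design than the default (fewer trials
#' or more volumes) and is the clean setting for parameter-recovery tests.
#'
#' @param n_runs number of runs.
#' @param volumes_per_run volumes acquired per run.
#' @param tr repetition time in seconds.
#' @param baseline_s initial fixation baseline per run (s).
#' @param trials_per_condition trials of each condition per run.
#' @param conditions condition labels.
#' @param mode `"dense"` (randomized rapid event-related ISI) or
#'   `"isolated"`.
#' @param min_isi_s minimum onset spacing in isolated mode (s).
#' @param seed integer seed; the schedule is deterministic per seed.
#' @return object of class `paradigm`: list with the design fields and an
#'   `onsets` data.frame (`run`, `onset_s`, `condition`).
#' @examples
#' par <- generate_paradigm(seed = 1)
#' paradigm_summary(par)$mean_isi_onset_s
#' @export
generate_paradigm <- function(n_runs = 4, volumes_per_run = 164, tr = 2.5,
                              baseline_s = 10, trials_per_condition = 32,
                              conditions = c("C", "IC", "N"),
                              mode = c("dense", "isolated"),
                              min_isi_s = 20, seed = 1) {
  mode <- match.arg(mode)
  n_trials_run <- trials_per_condition * length(conditions)
  first_slot <- ceiling(baseline_s / tr)       # volume index (0-based)
  slots <- first_slot:(volumes_per_run - 1L)
  spacing <- if (mode == "isolated") ceiling(min_isi_s / tr) else 1L
  capacity <- if (spacing == 1L) length(slots)
              else floor((length(slots) - 1L) / spacing) + 1L
  if (n_trials_run > capacity)
    stop(sprintf(
      "over-subscribed run: %d trials requested but only %d onset slots fit",
      n_trials_run, capacity), call. = FALSE)

  onsets <- local({
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    do.call(rbind, lapply(seq_len(n_runs), function(r) {
      chosen <- if (spacing == 1L) {
        sort(sample(slots, n_trials_run))
      } else {
        # random subset of the maximal evenly spaced slot family, jittered
        base <- slots[1L] + spacing * (seq_len(capacity) - 1L)
        sort(sample(base, n_trials_run))
      }
      cond <- sample(rep(conditions, trials_per_condition))
      data.frame(run = r, onset_s = chosen * tr, condition = cond)
    }))
  })
  structure(list(n_runs = n_runs, volumes_per_run = volumes_per_run,
                 tr = tr, baseline_s = baseline_s,
                 trials_per_condition = trials_per_condition,
                 conditions = conditions, mode = mode,
                 run_duration_s = volumes_per_run * tr,
                 seed = seed, onsets = onsets),
            class = "paradigm")
}

#' @export
print.paradigm <- function(x, ...) {
  cat(sprintf(
    "<paradigm> %d runs x %d volumes, TR %g s, %d trials/condition/run (%s), mode %s\n",
    x$n_runs, x$volumes_per_run, x$tr, x$trials_per_condition,
    paste(x$conditions, collapse = "/"), x$mode))
  invisible(x)
}

#' Summary statistics of a design
#'
#' Reports the mean inter-stimulus interval under both common definitions:
#' onset-to-onset (total acquisition duration divided by trial count) and
#' the mean gap between consecutive onsets within runs.
#'
#' @param paradigm a [generate_paradigm()] object.
#' @return list with `n_trials`, `total_duration_s`, `mean_isi_onset_s`,
#'   `mean_gap_s`.
#' @export
paradigm_summary <- function(paradigm) {
  stopifnot(inherits(paradigm, "paradigm"))
  n <- nrow(paradigm$onsets)
  total <- paradigm$n_runs * paradigm$run_duration_s
  gaps <- unlist(lapply(split(paradigm$onsets$onset_s, paradigm$onsets$run),
                        function(o) diff(sort(o))))
  list(n_trials = n, total_duration_s = total,
       mean_isi_onset_s = total / n,
       mean_gap_s = mean(gaps))
}

#' Ground truth for synthetic subjects
#'
#' Bundles everything needed to generate one synthetic subject's BOLD with
#' known parameters: the regional capacities, per-condition input
#' information, the inhibitory/secondary-excitatory structure of the trial
#' response, the HRF and the noise law. Per trial of condition `cond`, the
#' event train receives an excitatory impulse of `alpha[cond]` bits at the
#' trial onset, an inhibitory impulse of `b_frac * alpha[cond]` bits at
#' onset + `T0`, and a secondary excitatory impulse of
#' `c_frac * alpha[cond]` bits at onset + `T1`.
#'
#' @param ipc an [ipc_params()] object (p, m, c_loss).
#' @param alpha named vector of input information per condition (bits);
#'   emulating the flanker finding, defaults satisfy `alpha_IC > alpha_C`.
#' @param b_frac inhibitory amount as a fraction of the excitatory input.
#' @param c_frac secondary excitatory amount as a fraction of the input.
#' @param T0 inhibitory onset delay after the trial onset (s).
#' @param T1 secondary excitatory onset delay (s, >= T0).
#' @param hrf an [hrf_params()] object.
#' @param noise a [noise_model()].
#' @param error_rate fraction of trials dropped at random, emulating the
#'   exclusion of incorrect behavioural responses (default 0).
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(ipc = ipc_params(p = 1, m = 1.25),
                         alpha = c(C = 1, IC = 1.3, N = 0.9),
                         b_frac = 0.6, c_frac = 0.15,
                         T0 = 2.0, T1 = 5.0,
                         hrf = hrf_params(), noise = noise_model(),
                         error_rate = 0) {
  stopifnot(inherits(ipc, "ipc_params"), inherits(hrf, "hrf_params"),
            inherits(noise, "noise_model"))
  if (b_frac < 0 || c_frac < 0)
    stop("'b_frac' and 'c_frac' must be >= 0", call. = FALSE)
  if (T1 < T0) stop("'T1' must not precede 'T0'", call. = FALSE)
  if (error_rate < 0 || error_rate >= 1)
    stop("'error_rate' must lie in [0, 1)", call. = FALSE)
  structure(list(ipc = ipc, alpha = alpha, b_frac = b_frac, c_frac = c_frac,
                 T0 = T0, T1 = T1, hrf = hrf, noise = noise,
                 error_rate = error_rate),
            class = "ground_truth")
}

# two_state_params implied by a ground truth for one condition
truth_two_state <- function(truth, condition) {
  k <- truth$ipc$p / truth$ipc$m
  a <- truth$ipc$c_loss * truth$alpha[[condition]] / truth$ipc$m
  # onset-referenced component amplitudes, re-expressed at the reference
  # times T and 2T used by the fitted family
  b_on <- truth$b_frac * a
  c_on <- truth$c_frac * a
  two_state_params(a = a,
                   b = b_on * exp(k * (truth$T0 - 2.5)),
                   c_amp = c_on * exp(k * (truth$T1 - 5.0)),
                   k = k, T0 = truth$T0, T1 = truth$T1, T_ref = 2.5)
}

#' Generate one synthetic subject's BOLD
#'
#' Forward chain with known ground truth: build the per-run event trains
#' from the trial onsets, simulate neuronal activity with [simulate_ipc()]
#' on a fine grid, convolve with the HRF ([convolve_bold()]), sample at the
#' TR and add measurement noise ([sample_and_noise()]). Runs are simulated
#' independently and the sampled volumes concatenated, matching separate
#' acquisitions.
#'
#' @param paradigm a [generate_paradigm()] design.
#' @param truth a [ground_truth()] object.
#' @param fine_dt internal simulation step in seconds (default 0.1).
#' @return list of class `synthetic_subject`: `bold` (sampled
#'   [time_series()] at TR, runs concatenated), `x` (fine-grid activity per
#'   run, list), `events` (per-run [event_train()] list), `paradigm`,
#'   `truth`, `n_dropped` (trials removed by the error-rate filter).
#' @export
generate_subject <- function(paradigm, truth, fine_dt = 0.1) {
  stopifnot(inherits(paradigm, "paradigm"), inherits(truth, "ground_truth"))
  tr <- paradigm$tr
  if (abs(tr / fine_dt - round(tr / fine_dt)) > 1e-8)
    stop("'fine_dt' must divide the TR", call. = FALSE)
  onsets <- paradigm$onsets
  n_dropped <- 0L
  if (truth$error_rate > 0) {
    keep <- stats::runif(nrow(onsets)) >= truth$error_rate
    n_dropped <- sum(!keep)
    onsets <- onsets[keep, , drop = FALSE]
  }
  grid <- seq(0, (paradigm$volumes_per_run - 1L) * tr, by = fine_dt)
  h <- hrf_kernel(truth$hrf, seq(0, 32, by = fine_dt))

  runs <- lapply(seq_len(paradigm$n_runs), function(r) {
    on_r <- onsets[onsets$run == r, , drop = FALSE]
    exc <- data.frame(time = numeric(0), amount = numeric(0))
    inh <- data.frame(time = numeric(0), amount = numeric(0))
    for (i in seq_len(nrow(on_r))) {
      a_bits <- truth$alpha[[on_r$condition[i]]]
      o <- on_r$onset_s[i]
      exc <- rbind(exc, data.frame(time = o, amount = a_bits))
      if (truth$b_frac > 0)
        inh <- rbind(inh, data.frame(time = o + truth$T0,
                                     amount = truth$b_frac * a_bits))
      if (truth$c_frac > 0)
        exc <- rbind(exc, data.frame(time = o + truth$T1,
                                     amount = truth$c_frac * a_bits))
    }
    ev <- event_train(excitatory = exc[order(exc$time), , drop = FALSE],
                      inhibitory = if (nrow(inh)) inh[order(inh$time), ,
                                                      drop = FALSE] else NULL)
    x <- simulate_ipc(ev, truth$ipc, x0 = 0, grid = grid)
    y <- convolve_bold(x, h)
    list(events = ev, x = x, y = sample_and_noise(y, tr, noise_model()))
  })

  y_all <- unlist(lapply(runs, function(r) r$y$values))
  y_all <- y_all + draw_noise(truth$noise, length(y_all))
  structure(list(bold = time_series(y_all, dt = tr, t0 = 0),
                 x = lapply(runs, `[[`, "x"),
                 events = lapply(runs, `[[`, "events"),
                 paradigm = paradigm, truth = truth,
                 n_dropped = n_dropped),
            class = "synthetic_subject")
}

#' Trial-averaged BOLD impulse response
#'
#' For every onset of the requested condition, extracts the BOLD samples at
#' offsets `0, tr, ..., window_s` after the onset and averages across
#' trials. With the default 15 s window at TR 2.5 s the impulse response is
#' resolved to exactly 7 points. Trials whose window would run past the end
#' of their run are dropped with a warning reporting the count.
#'
#' @param y sampled BOLD [time_series()] at the TR, runs concatenated in
#'   acquisition order (as produced by [generate_subject()]).
#' @param paradigm the [generate_paradigm()] design that produced `y`.
#' @param condition condition label to average.
#' @param window_s averaging window in seconds; multiple of the TR.
#' @return A [time_series()] of the trial-averaged impulse response at the
#'   TR, with attribute `n_trials` (trials averaged).
#' @export
trial_average <- function(y, paradigm, condition, window_s = 15) {
  stopifnot(inherits(y, "ipc_ts"), inherits(paradigm, "paradigm"))
  tr <- paradigm$tr
  if (abs(y$dt - tr) > 1e-9)
    stop("'y' must be sampled at the design TR", call. = FALSE)
  n_off <- round(window_s / tr)
  if (abs(window_s / tr - n_off) > 1e-8)
    stop("'window_s' must be a multiple of the TR", call. = FALSE)
  offs <- 0:n_off
  on <- paradigm$onsets[paradigm$onsets$condition == condition, ,
                        drop = FALSE]
  if (nrow(on) == 0L)
    stop(sprintf("no trials of condition '%s' in the design", condition),
         call. = FALSE)
  vol_per_run <- paradigm$volumes_per_run
  acc <- numeric(n_off + 1L)
  used <- 0L
  dropped <- 0L
  for (i in seq_len(nrow(on))) {
    i0 <- round(on$onset_s[i] / tr)           # volume index within run
    if (i0 + n_off > vol_per_run - 1L) {
      dropped <- dropped + 1L
      next
    }
    gidx <- (on$run[i] - 1L) * vol_per_run + i0 + 1L + offs
    acc <- acc + y$values[gidx]
    used <- used + 1L
  }
  if (dropped > 0L)
    warning(sprintf("%d trial(s) dropped: window exceeds run end", dropped),
            call. = FALSE)
  if (used == 0L)
    stop("no complete trials available for averaging", call. = FALSE)
  out <- time_series(acc / used, dt = tr, t0 = 0)
  attr(out, "n_trials") <- used
  out
}
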