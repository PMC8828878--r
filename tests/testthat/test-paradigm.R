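test_that("default flanker-like design has the expected ISI structure", {
  par <- generate_paradigm(seed = 1)
  s <- paradigm_summary(par)
  expect_equal(s$n_trials, 384)
  expect_equal(round(s$mean_isi_onset_s, 2), 4.27)
  expect_true(all(par$onsets$onset_s %% 2.5 == 0))
  expect_true(all(par$onsets$onset_s >= par$baseline_s))
  # both ISI definitions are reported
  expect_true(is.finite(s$mean_gap_s))
})

test_that("schedules are valid and deterministic per seed", {
  p1 <- generate_paradigm(seed = 9)
  p2 <- generate_paradigm(seed = 9)
  p3 <- generate_paradigm(seed = 10)
  expect_identical(p1$onsets, p2$onsets)
  expect_false(identical(p1$onsets, p3$onsets))
  # exact condition counts and no shared onsets within a run
  for (r in 1:4) {
    on_r <- p1$onsets[p1$onsets$run == r, ]
    expect_equal(unname(table(on_r$condition)[c("C", "IC", "N")]),
                 rep(32L, 3), ignore_attr = TRUE)
    expect_false(any(duplicated(on_r$onset_s)))
  }
  expect_error(generate_paradigm(trials_per_condition = 60),
               "over-subscribed")
  # isolated mode honours the minimum spacing
  iso <- isolated_paradigm(seed = 3)
  gaps <- unlist(lapply(split(iso$onsets$onset_s, iso$onsets$run),
                        function(o) diff(sort(o))))
  expect_true(all(gaps >= 65))
})

test_that("single-trial subject equals the convolved two-state response", {
  par <- generate_paradigm(n_runs = 1, volumes_per_run = 200, tr = 2.5,
                           baseline_s = 10, trials_per_condition = 1,
                           conditions = "C", mode = "isolated",
                           min_isi_s = 65, seed = 5)
  truth <- default_truth()
  subj <- generate_subject(par, truth)
  onset <- par$onsets$onset_s[1]
  g <- seq(0, (par$volumes_per_run - 1) * 2.5, by = 0.1)
  ts2 <- ipcmodel:::truth_two_state(truth, "C")
  x_ref <- two_state_response(ts2, g - onset)
  x_ref <- time_series(x_ref$values, dt = 0.1)
  y_ref <- sample_and_noise(
    convolve_bold(x_ref, hrf_kernel(truth$hrf, seq(0, 32, by = 0.1))), 2.5)
  expect_lt(max(abs(subj$bold$values - y_ref$values)), 1e-10)
})

test_that("zero input information yields flat BOLD plus noise only", {
  par <- isolated_paradigm(seed = 2)
  truth <- ground_truth(alpha = c(C = 0, IC = 0))
  subj <- generate_subject(par, truth)
  expect_true(all(subj$bold$values == 0))
  truth_n <- ground_truth(alpha = c(C = 0, IC = 0),
                          noise = noise_model("white", 0.01, seed = 3))
  subj_n <- generate_subject(par, truth_n)
  expect_equal(stats::sd(subj_n$bold$values), 0.01, tolerance = 0.15)
})

test_that("trial averaging resolves a 7-point impulse response", {
  par <- isolated_paradigm(seed = 4)
  truth <- default_truth()
  subj <- generate_subject(par, truth)
  irf <- trial_average(subj$bold, par, "C", window_s = 15)
  expect_length(irf$values, 7L)
  expect_equal(irf$dt, 2.5)
  expect_equal(attr(irf, "n_trials"), 8L)
})

test_that("trial averaging matches a naive per-trial loop", {
  par <- generate_paradigm(n_runs = 2, volumes_per_run = 100, tr = 2.5,
                           baseline_s = 10, trials_per_condition = 5,
                           conditions = c("C", "IC"), seed = 6)
  set.seed(7)
  y <- time_series(rnorm(200), dt = 2.5)
  irf <- trial_average(y, par, "IC", window_s = 15)
  on <- par$onsets[par$onsets$condition == "IC", ]
  rows <- list()
  for (i in seq_len(nrow(on))) {
    i0 <- on$onset_s[i] / 2.5 + (on$run[i] - 1) * 100
    if (on$onset_s[i] / 2.5 + 6 <= 99)
      rows[[length(rows) + 1]] <- y$values[i0 + 1 + 0:6]
  }
  expect_equal(irf$values, colMeans(do.call(rbind, rows)),
               tolerance = 1e-14)

  # constant signal averages to itself
  yc <- time_series(rep(3.2, 200), dt = 2.5)
  expect_equal(trial_average(yc, par, "C")$values, rep(3.2, 7),
               tolerance = 1e-14)

  # trials running past the run end are dropped with a warning
  par2 <- generate_paradigm(n_runs = 1, volumes_per_run = 20, tr = 2.5,
                            baseline_s = 0, trials_per_condition = 18,
                            conditions = "C", seed = 8)
  y2 <- time_series(rnorm(20), dt = 2.5)
  expect_warning(trial_average(y2, par2, "C"), "dropped")
})

test_that("averaging shrinks white noise like 1/sqrt(n)", {
  par <- generate_paradigm(n_runs = 4, volumes_per_run = 164, tr = 2.5,
                           baseline_s = 10, trials_per_condition = 32,
                           seed = 11)
  sigma <- 1
  set.seed(12)
  # pool averaged points over independent noise realizations so the SD
  # estimate is stable enough to check the 1/sqrt(n) scaling to 20%
  pts <- unlist(lapply(1:10, function(i) {
    y <- time_series(rnorm(4 * 164, sd = sigma), dt = 2.5)
    suppressWarnings(trial_average(y, par, "C", window_s = 15)$values)
  }))
  n <- 128  # trials averaged per condition
  expect_equal(stats::sd(pts), sigma / sqrt(n), tolerance = 0.2)
})

test_that("the error-rate filter drops trials", {
  par <- isolated_paradigm(seed = 13)
  truth <- default_truth(error_rate = 0.3)
  set.seed(14)
  subj <- generate_subject(par, truth)
  expect_gt(subj$n_dropped, 0)
})
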