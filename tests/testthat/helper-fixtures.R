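# Shared builders for the test suite. Everything is generated in code; no
# stored fixtures.

canonical_hrf <- function() hrf_params()  # peak-normalized double gamma

# sparse design whose trials are far enough apart that neither the
# neuronal response (~15 s) nor the hemodynamic tail (~32 s) of one trial
# reaches the averaging window of the next
isolated_paradigm <- function(n_runs = 1, trials_per_condition = 8,
                              conditions = c("C", "IC"), seed = 42) {
  generate_paradigm(n_runs = n_runs, volumes_per_run = 410, tr = 2.5,
                    baseline_s = 10,
                    trials_per_condition = trials_per_condition,
                    conditions = conditions, mode = "isolated",
                    min_isi_s = 65, seed = seed)
}

default_truth <- function(k = 0.8, m = 1.25, alpha_C = 1, ratio = 1.3,
                          noise = noise_model(), ...) {
  ground_truth(ipc = ipc_params(p = k * m, m = m),
               alpha = c(C = alpha_C, IC = ratio * alpha_C),
               b_frac = 0.6, c_frac = 0.15, T0 = 2, T1 = 5,
               noise = noise, ...)
}

# random two-state parameter draw used by recovery tests; onsets on the
# 0.1 s grid within the fitted search ranges
random_two_state <- function(k = NULL) {
  if (is.null(k)) k <- stats::runif(1, 0.2, 2)
  two_state_params(a = stats::runif(1, 0.5, 1.5),
                   b = stats::runif(1, 0.05, 0.4),
                   c_amp = stats::runif(1, 0.02, 0.2),
                   k = k,
                   T0 = round(stats::runif(1, 0.5, 4.5), 1),
                   T1 = round(stats::runif(1, 5, 9.5), 1))
}

expect_ts_equal <- function(a, b, tol = 1e-12) {
  expect_s3_class(a, "ipc_ts")
  expect_s3_class(b, "ipc_ts")
  expect_equal(a$dt, b$dt, tolerance = 1e-12)
  expect_lt(max(abs(a$values - b$values)), tol)
}
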