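test_that("activity-domain fit recovers known two-state parameters", {
  set.seed(30)
  g <- seq(0, 15, by = 0.1)
  for (draw in 1:5) {
    truth <- random_two_state()
    fit <- fit_two_state(two_state_response(truth, g))
    expect_equal(fit$k, truth$k, tolerance = 1e-3)
    expect_equal(fit$a, truth$a, tolerance = 1e-3)
    expect_equal(fit$b, truth$b, tolerance = 1e-2)
    expect_equal(fit$c_amp, truth$c_amp, tolerance = 1e-2)
    expect_lte(abs(fit$T0 - truth$T0), 0.1 + 1e-9)
    expect_lte(abs(fit$T1 - truth$T1), 0.1 + 1e-9)
  }
})

test_that("a pure exponential is fitted with null delayed components", {
  g <- seq(0, 15, by = 0.1)
  x <- two_state_response(two_state_params(a = 1.1, k = 0.6), g)
  fit <- fit_two_state(x)
  expect_lte(fit$b, 1e-6)
  expect_lte(fit$c_amp, 1e-6)
  expect_equal(fit$k, 0.6, tolerance = 1e-4)
  expect_error(fit_two_state(time_series(rep(0, 151), dt = 0.1)),
               "degenerate")
})

test_that("decay-rate recovery stays calibrated under measurement noise", {
  # Monte-Carlo at 2% of peak white noise on the fine-grid response
  truth <- two_state_params(a = 0.8, b = 0.25, c_amp = 0.12, k = 0.8,
                            T0 = 2, T1 = 5)
  g <- seq(0, 15, by = 0.1)
  x0 <- two_state_response(truth, g)
  set.seed(31)
  errs <- replicate(40, {
    xn <- time_series(x0$values +
                        rnorm(length(g), sd = 0.02 * max(x0$values)), 0.1)
    abs(fit_two_state(xn)$k - truth$k) / truth$k
  })
  expect_lt(stats::median(errs), 0.1)
})

test_that("BOLD-domain refinement makes the inversion exact when noise-free", {
  par <- isolated_paradigm(seed = 32)
  truth <- default_truth(k = 1.4)
  subj <- generate_subject(par, truth)
  y <- trial_average(subj$bold, par, "C", window_s = 15)
  fr <- suppressMessages(fit_bold_response(y, truth$hrf))
  expect_equal(fr$params$k, 1.4, tolerance = 1e-3)
  expect_lt(fr$mse, 1e-10)
})

test_that("HRF selection identifies the generating response delay", {
  par <- isolated_paradigm(seed = 33)
  truth <- default_truth(hrf = hrf_params(alpha1 = 6))
  subj <- generate_subject(par, truth)
  y <- trial_average(subj$bold, par, "C", window_s = 15)
  cand <- data.frame(alpha1 = c(4, 5, 6, 7, 8), alpha2 = 16)
  sel <- suppressMessages(select_hrf(y, "flexible", cand))
  expect_equal(sel$hrf$alpha1, 6)
  # argmin contract: the winner's MSE is minimal over the grid
  mses <- vapply(cand$alpha1, function(a1)
    suppressMessages(fit_bold_response(y, hrf_params(alpha1 = a1,
                                                     alpha2 = 16)))$mse, 0)
  expect_equal(sel$fit$mse, min(mses), tolerance = 1e-10)
  # single candidate: returned as-is
  one <- suppressMessages(select_hrf(y, "flexible",
                                     data.frame(alpha1 = 5, alpha2 = 16)))
  expect_equal(one$hrf$alpha1, 5)
  expect_error(select_hrf(y, "flexible", data.frame()), "non-empty")
})

test_that("fixed mode applies the reference dataset's HRF everywhere", {
  par <- isolated_paradigm(seed = 34)
  truth <- default_truth(hrf = hrf_params(alpha1 = 7))
  subj <- generate_subject(par, truth)
  ys <- list(old_IC = trial_average(subj$bold, par, "IC", window_s = 15),
             young_C = trial_average(subj$bold, par, "C", window_s = 15))
  cand <- data.frame(alpha1 = c(5, 7), alpha2 = 16)
  out <- suppressMessages(select_hrf(ys, "fixed", cand,
                                     reference = "old_IC"))
  expect_equal(out$old_IC$hrf$alpha1, 7)
  expect_equal(out$young_C$hrf$alpha1, 7)  # inherited from the reference
})

test_that("derived capacities follow the identifiable ratios", {
  p <- two_state_params(a = 2, k = 1)
  d <- derive_capacities(p)
  expect_equal(d$rel_processing, 0.5)  # p/alpha = k / a
  expect_equal(d$rel_storage, 0.5)     # m/alpha = 1 / a
  expect_equal(d$t_const, 1)           # T_c = 1/k
  # scale invariance: doubling a and the reference together leaves T_c
  p2 <- two_state_params(a = 4, k = 1)
  expect_equal(derive_capacities(p2, reference_amp = 4)$t_const,
               derive_capacities(p, reference_amp = 2)$t_const)
  expect_error(derive_capacities(p, reference_amp = 0), "positive")
  # time-to-peak of the predicted BOLD is located on the dense grid
  d2 <- derive_capacities(p, hrf = canonical_hrf())
  expect_gt(d2$t_peak, 0)
  expect_lt(d2$t_peak, 15)
})

test_that("shared-k fitting recovers the condition amplitude ratio", {
  par <- isolated_paradigm(seed = 35)
  truth <- default_truth(ratio = 1.3)
  subj <- generate_subject(par, truth)
  irfs <- lapply(c(C = "C", IC = "IC"), function(cond)
    trial_average(subj$bold, par, cond, window_s = 15))
  cfg <- deconv_config()
  xf <- lapply(irfs, function(y)
    spline_upsample(suppressMessages(deconvolve_ls(y, truth$hrf, cfg)),
                    0.1))
  fits <- fit_two_state_shared(xf, y_list = irfs, hrf = truth$hrf)
  expect_equal(fits$IC$a / fits$C$a, 1.3, tolerance = 1e-4)
  expect_identical(fits$C$k, fits$IC$k)
  # IC peak activity exceeds C when alpha_IC > alpha_C
  expect_gt(fits$IC$a, fits$C$a)
})

test_that("prediction scoring is an elementwise mean square", {
  par <- isolated_paradigm(seed = 36)
  truth <- default_truth()
  subj <- generate_subject(par, truth)
  y <- trial_average(subj$bold, par, "C", window_s = 15)
  ts2 <- ipcmodel:::truth_two_state(truth, "C")
  fr <- predict_and_score(ts2, truth$hrf, y)
  # the generating parameters reproduce their own BOLD
  expect_lt(fr$mse, 1e-12)
  # arithmetic oracle
  expect_equal(fr$mse, mean((y$values - fr$y_pred$values)^2),
               tolerance = 1e-15)
  # MSE ignores a common shift of the time origin
  y_shift <- time_series(y$values, dt = y$dt, t0 = 10)
  fr2 <- predict_and_score(ts2, truth$hrf, y_shift)
  expect_equal(fr2$mse, fr$mse, tolerance = 1e-15)
})
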