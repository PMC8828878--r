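test_that("step response has the abrupt onset x(0) = alpha/m and decays on T_c", {
  g <- seq(0, 10, by = 0.1)
  a0 <- 0.8  # alpha/m
  x <- step_response(a0, 0.5, g)
  expect_identical(x$values[1], a0)
  # at one time constant T_c = 1/k = 2 s the activity is down to 1/e
  x1 <- step_response(1, 0.5, g)
  expect_equal(x1$values[ts_time(x1) == 2], exp(-1), tolerance = 1e-12)
  # pre-stimulus activity is zero
  g2 <- seq(-2, 5, by = 0.1)
  x2 <- step_response(1, 1, g2)
  expect_true(all(x2$values[g2 < 0] == 0))
  expect_error(step_response(1, 0, g), "positive")
})

test_that("closed-form step response matches an independent stiff ODE solve", {
  skip_if_not_installed("deSolve")
  g <- seq(0, 15, by = 0.01)
  a0 <- 0.8
  k <- 0.4
  x <- step_response(a0, k, g)
  # impulse folded into the initial condition, integrated by lsoda
  sol <- deSolve::lsoda(y = c(x = a0), times = g,
                        func = function(t, y, p) list(-p$k * y),
                        parms = list(k = k), rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(x$values - sol[, "x"])), 1e-8)
})

test_that("exact-propagator simulation agrees with a generic stiff solver", {
  skip_if_not_installed("deSolve")
  set.seed(1)
  g <- seq(0, 20, by = 0.01)
  for (i in 1:20) {
    p <- runif(1, 0.2, 3)
    m <- runif(1, 0.5, 4)
    c_loss <- sample(c(1, runif(1)), 1)
    alpha <- runif(1, 0.5, 2)
    ev <- event_train(excitatory = data.frame(time = 0, amount = alpha))
    x <- simulate_ipc(ev, ipc_params(p, m, c_loss), grid = g)
    sol <- deSolve::lsoda(y = c(x = c_loss * alpha / m), times = g,
                          func = function(t, y, pa) list(-pa$k * y),
                          parms = list(k = p / m),
                          rtol = 1e-10, atol = 1e-12)
    expect_lt(max(abs(x$values - sol[, "x"])), 1e-8)
  }
})

test_that("event-train response is the superposition of step responses", {
  set.seed(2)
  g <- seq(0, 30, by = 0.05)
  k <- 0.7
  m <- 2
  times <- sort(round(runif(3, 0, 10), 1))
  amounts <- runif(3, 0.2, 1.5)
  ev <- event_train(excitatory = data.frame(time = times, amount = amounts))
  x <- ei_response(ev, k, m, g)
  oracle <- numeric(length(g))
  for (i in 1:3) {
    s <- step_response(amounts[i] / m, k, g - times[i])
    oracle <- oracle + s$values
  }
  expect_lt(max(abs(x$values - oracle)), 1e-12)

  # exact cancellation: matched inhibitory event at the same time
  ev2 <- event_train(excitatory = data.frame(time = 0, amount = 1),
                     inhibitory = data.frame(time = 0, amount = 1))
  expect_true(all(ei_response(ev2, 1, 1, g)$values == 0))
  expect_error(
    event_train(excitatory = data.frame(time = 0, amount = -1)), "amount")
})

test_that("two-state response equals x_E - x_I of the switched model", {
  g <- seq(0, 20, by = 0.01)
  k <- 0.8; m <- 1.5; alpha <- 1.2; beta <- 0.7; T0 <- 2.5
  ev <- event_train(excitatory = data.frame(time = 0, amount = alpha),
                    inhibitory = data.frame(time = T0, amount = beta))
  x <- ei_response(ev, k, m, g)
  x_E <- step_response(alpha / m, k, g)$values
  x_I <- step_response(beta / m, k, g - T0)$values
  expect_lt(max(abs(x$values - (x_E - x_I))), 1e-12)
})

test_that("impulse simulation reduces to the step response", {
  g <- seq(0, 15, by = 0.01)
  alpha <- 1.4
  pars <- ipc_params(p = 1, m = 2)
  ev <- event_train(excitatory = data.frame(time = 0, amount = alpha))
  x <- simulate_ipc(ev, pars, grid = g)
  expect_ts_equal(x, step_response(alpha / pars$m, pars$p / pars$m, g),
                  tol = 1e-12)
})

test_that("a fully lossy region shows no activity", {
  g <- seq(0, 15, by = 0.01)
  ev <- event_train(excitatory = data.frame(time = c(0, 3), amount = c(1, 2)))
  x <- simulate_ipc(ev, ipc_params(p = 1, m = 1, c_loss = 0), grid = g)
  expect_true(all(x$values == 0))
})

test_that("sustained arrival converges to the fixed point c*H0/p", {
  g <- seq(0, 80, by = 0.01)
  H0 <- 0.6
  arrival <- time_series(rep(H0, length(g)), dt = 0.01)
  pars <- ipc_params(p = 1.5, m = 1, c_loss = 0.8)
  x <- simulate_ipc(arrival, pars, grid = g)
  expect_equal(x$values[length(g)], pars$c_loss * H0 / pars$p,
               tolerance = 1e-6)
})

test_that("information conservation holds along simulated trajectories", {
  g <- seq(0, 15, by = 0.001)
  alpha <- 1.3
  ev <- event_train(excitatory = data.frame(time = 0, amount = alpha))

  # lossless: I = I_p + I_m at every grid point
  pars <- ipc_params(p = 1.2, m = 1.5)
  x <- simulate_ipc(ev, pars, grid = g)
  acc <- information_accounting(x, ev, pars)
  expect_lt(max(abs(acc$residual$values)), 1e-6 * alpha)
  # complete processing of a finite input: I_p -> alpha, I_m -> 0
  x_long <- simulate_ipc(ev, pars, grid = seq(0, 60, by = 0.001))
  acc_long <- information_accounting(x_long, ev, pars)
  n <- length(acc_long$I_p$values)
  expect_equal(acc_long$I_p$values[n], alpha, tolerance = 1e-3)
  expect_lt(acc_long$I_m$values[n], 1e-3)

  # lossy: c*I = I_p + I_m
  pars2 <- ipc_params(p = 1.2, m = 1.5, c_loss = 0.5)
  x2 <- simulate_ipc(ev, pars2, grid = g)
  acc2 <- information_accounting(x2, ev, pars2)
  expect_lt(max(abs(acc2$residual$values)), 1e-6 * alpha)
})

test_that("responses are linear in the event train", {
  g <- seq(0, 25, by = 0.01)
  pars <- ipc_params(p = 1, m = 2)
  ev1 <- event_train(excitatory = data.frame(time = c(0, 4), amount = c(1, 0.5)))
  ev2 <- event_train(excitatory = data.frame(time = 2, amount = 0.8),
                     inhibitory = data.frame(time = 6, amount = 0.6))
  both <- event_train(
    excitatory = data.frame(time = c(0, 2, 4), amount = c(1, 0.8, 0.5)),
    inhibitory = data.frame(time = 6, amount = 0.6))
  x_sum <- simulate_ipc(ev1, pars, grid = g)$values +
    simulate_ipc(ev2, pars, grid = g)$values
  expect_lt(max(abs(simulate_ipc(both, pars, grid = g)$values - x_sum)),
            1e-12)
})

test_that("capacity monotonicities match the model's interpretation", {
  # with m fixed, T_c and the steady state both decrease in p
  ps <- c(0.5, 1, 2, 4)
  tc <- vapply(ps, function(p) ipc_params(p, m = 2)$t_const, 0)
  expect_true(all(diff(tc) < 0))
  g <- seq(0, 100, by = 0.05)
  H0 <- 1
  ss <- vapply(ps, function(p)
    simulate_ipc(time_series(rep(H0, length(g)), dt = 0.05),
                 ipc_params(p, m = 2), grid = g)$values[length(g)], 0)
  expect_true(all(diff(ss) < 0))
  # with alpha and p fixed, the onset activity alpha/m decreases in m
  ms <- c(0.5, 1, 2, 4)
  peak <- vapply(ms, function(m)
    simulate_ipc(event_train(excitatory = data.frame(time = 0, amount = 1)),
                 ipc_params(p = 1, m = m), grid = g)$values[1], 0)
  expect_true(all(diff(peak) < 0))
})

test_that("single-region DCM mapping is exact and invertible", {
  expect_equal(unclass(sdcm_map(ipc_params(p = 2, m = 4)))[c("sigma", "beta_in")],
               list(sigma = 0.5, beta_in = 0.25))
  set.seed(3)
  for (i in 1:100) {
    pars <- ipc_params(p = runif(1, 0.1, 5), m = runif(1, 0.1, 5),
                       c_loss = runif(1, 0.05, 1))
    back <- sdcm_inverse(sdcm_map(pars), c_loss = pars$c_loss)
    expect_equal(back$p, pars$p, tolerance = 1e-12)
    expect_equal(back$m, pars$m, tolerance = 1e-12)
  }
  expect_error(sdcm_inverse(sdcm_map(ipc_params(1, 1, 0.5)), c_loss = 0),
               "invertible")
})

test_that("the mapped S-DCM reproduces the IPC simulation exactly", {
  # independent exact-propagator integration of dx/dt = -sigma x + beta e(t)
  g <- seq(0, 20, by = 0.01)
  pars <- ipc_params(p = 1.3, m = 1.7, c_loss = 0.9)
  sd <- sdcm_map(pars)
  ev <- event_train(excitatory = data.frame(time = c(0, 5), amount = c(1, 0.7)),
                    inhibitory = data.frame(time = 8, amount = 0.4))
  x_ipc <- simulate_ipc(ev, pars, grid = g)
  decay <- exp(-sd$sigma * 0.01)
  x <- numeric(length(g))
  jump <- numeric(length(g))
  sgn <- ifelse(ev$sign == "E", 1, -1)
  for (i in seq_len(nrow(ev))) {
    idx <- round(ev$onset_s[i] / 0.01) + 1
    # beta * impulse area = (c/m) * amount, the same jump the IPC model takes
    jump[idx] <- jump[idx] + sgn[i] * sd$beta_in * ev$amount_bits[i]
  }
  x[1] <- jump[1]
  for (i in seq_len(length(g) - 1)) x[i + 1] <- x[i] * decay + jump[i + 1]
  expect_lt(max(abs(x - x_ipc$values)), 1e-12)
})
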