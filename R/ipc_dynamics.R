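#' Information processing capacity (IPC) parameters
#'
#' The IPC model describes the normalized neuronal activity `x(t)` of a
#' single-state brain region by the first-order linear ODE
#' \deqn{\dot x(t) = -\frac{p}{m} x(t) + \frac{c}{m} H(t),}
#' where `p` is the information processing capacity (bit/s), `m` the input
#' storage capacity (bits), `H(t)` the information arrival rate (bit/s) and
#' `c` the retained-information fraction (`c = 1`: lossless region). The
#' circuit time constant is `T_c = m/p` seconds.
#'
#' @param p processing capacity in bit/s (> 0).
#' @param m input storage capacity in bits (> 0).
#' @param c_loss retained-information fraction in \[0, 1\] (default 1,
#'   lossless).
#' @return An object of class `ipc_params`.
#' @examples
#' pars <- ipc_params(p = 2, m = 4)
#' pars$t_const  # m/p = 2 s
#' @export
ipc_params <- function(p, m, c_loss = 1) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0)
    stop("'p' must be a positive number (bit/s)", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m <= 0)
    stop("'m' must be a positive number (bits)", call. = FALSE)
  if (!is.numeric(c_loss) || length(c_loss) != 1L || c_loss < 0 || c_loss > 1)
    stop("'c_loss' must lie in [0, 1]", call. = FALSE)
  structure(list(p = p, m = m, c_loss = c_loss, t_const = m / p),
            class = "ipc_params")
}

#' @export
print.ipc_params <- function(x, ...) {
  cat(sprintf("<ipc_params> p = %g bit/s, m = %g bits, c = %g, T_c = %g s\n",
              x$p, x$m, x$c_loss, x$t_const))
  invisible(x)
}

#' Timed information deliveries (event train)
#'
#' Excitatory and inhibitory information deliveries are modelled as signed
#' Dirac impulses in the arrival rate `H(t)`: an excitatory event of
#' `amount` bits at time `T` contributes `amount * delta(t - T)`. Inhibitory
#' events model the delayed inhibitory control signal of the two-state
#' excitation/inhibition response.
#'
#' @param excitatory data.frame with columns `time` (s) and `amount`
#'   (bits, >= 0), or NULL.
#' @param inhibitory same layout, or NULL.
#' @return An object of class `event_train`: data.frame with columns
#'   `onset_s`, `amount_bits`, `sign` (`"E"` or `"I"`), sorted by onset.
#' @examples
#' ev <- event_train(excitatory = data.frame(time = 0, amount = 2),
#'                   inhibitory = data.frame(time = 2.5, amount = 1.4))
#' @export
event_train <- function(excitatory = NULL, inhibitory = NULL) {
  as_part <- function(df, sign) {
    if (is.null(df) || nrow(df) == 0L)
      return(data.frame(onset_s = numeric(0), amount_bits = numeric(0),
                        sign = character(0)))
    if (!all(c("time", "amount") %in% names(df)))
      stop("event tables need columns 'time' and 'amount'", call. = FALSE)
    if (any(!is.finite(df$time)) || is.unsorted(df$time))
      stop("event times must be finite and sorted non-decreasing",
           call. = FALSE)
    if (any(df$amount < 0) || any(!is.finite(df$amount)))
      stop("event amounts must be finite and >= 0 bits", call. = FALSE)
    data.frame(onset_s = df$time, amount_bits = df$amount, sign = sign)
  }
  ev <- rbind(as_part(excitatory, "E"), as_part(inhibitory, "I"))
  ev <- ev[order(ev$onset_s, ev$sign), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_train", "data.frame")
  ev
}

ev_part <- function(events, sign) {
  events[events$sign == sign, , drop = FALSE]
}

#' Activity step response to an impulse of information
#'
#' An impulse of `alpha` bits arriving at `t = 0` in a region with storage
#' `m` and decay rate `k = p/m` produces the abrupt-onset exponential
#' \deqn{x(t) = a_0 e^{-kt} u(t), \qquad a_0 = \alpha/m,}
#' with `x(0-) = 0` and `x(0) = a0` (right-continuous onset response).
#'
#' @param a0 initial activity `alpha/m` (dimensionless, >= 0).
#' @param k decay rate `p/m` in 1/s (> 0).
#' @param grid uniform time grid in seconds (may include t < 0, where the
#'   response is zero).
#' @return A [time_series()] of `x(t)` on the grid.
#' @examples
#' x <- step_response(1, 0.5, seq(0, 10, by = 0.1))
#' x$values[ts_time(x) == 2]  # exp(-1) at one time constant
#' @export
step_response <- function(a0, k, grid) {
  if (!is.numeric(a0) || length(a0) != 1L || a0 < 0)
    stop("'a0' must be a single number >= 0", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("'k' must be a single positive rate (1/s)", call. = FALSE)
  dt <- check_uniform_grid(grid)
  v <- ifelse(grid >= 0, a0 * exp(-k * pmax(grid, 0)), 0)
  time_series(v, dt = dt, t0 = grid[1])
}

#' Two-state / multi-event excitation-inhibition response
#'
#' Superposition of decaying exponentials, one per delivery:
#' \deqn{x(t) = \sum_i \frac{\alpha_i}{m} e^{-k(t - T_{E,i})} u(t - T_{E,i})
#'   - \sum_j \frac{\beta_j}{m} e^{-k(t - T_{I,j})} u(t - T_{I,j}).}
#' All components share the decay rate `k = p/m` because they traverse the
#' same regional circuit; the response is linear in the event amounts.
#'
#' @param events an [event_train()].
#' @param k decay rate `p/m` in 1/s (> 0).
#' @param m storage capacity in bits (> 0) converting bits to activity.
#' @param grid uniform time grid in seconds.
#' @return A [time_series()] of `x(t)`.
#' @export
ei_response <- function(events, k, m, grid) {
  stopifnot(inherits(events, "event_train"))
  if (k <= 0) stop("'k' must be positive", call. = FALSE)
  if (m <= 0) stop("'m' must be positive", call. = FALSE)
  dt <- check_uniform_grid(grid)
  v <- numeric(length(grid))
  sgn <- ifelse(events$sign == "E", 1, -1)
  for (i in seq_len(nrow(events))) {
    tau <- grid - events$onset_s[i]
    on <- tau >= 0
    v[on] <- v[on] + sgn[i] * (events$amount_bits[i] / m) * exp(-k * tau[on])
  }
  time_series(v, dt = dt, t0 = grid[1])
}

#' Simulate the IPC model under an arbitrary arrival process
#'
#' Integrates \eqn{\dot x = -(p/m) x + (c/m) H(t)} on a uniform grid using
#' the exact one-step exponential propagator of the linear constant-
#' coefficient ODE: over one step `dt`,
#' \eqn{x_{n+1} = x_n e^{-k\,dt} + (c/m) H_n (1 - e^{-k\,dt})/k}
#' for sampled arrivals (zero-order hold), while an impulse of `alpha` bits
#' at time `tau` adds an instantaneous jump `c * alpha / m` at the grid
#' point carrying `tau` (right-continuous convention: the sample at `tau`
#' takes the post-jump value). Impulse times are snapped to the nearest grid
#' point.
#'
#' @param arrival either an [event_train()] (impulsive deliveries) or a
#'   [time_series()] sampling `H(t)` in bit/s on the same grid.
#' @param params an [ipc_params()] object.
#' @param x0 initial activity at the first grid point (default 0), before
#'   any impulse at that time.
#' @param grid uniform time grid in seconds.
#' @return A [time_series()] of `x(t)`.
#' @examples
#' ev <- event_train(excitatory = data.frame(time = 0, amount = 2))
#' x <- simulate_ipc(ev, ipc_params(p = 1, m = 2), grid = seq(0, 15, 0.01))
#' @export
simulate_ipc <- function(arrival, params, x0 = 0, grid) {
  stopifnot(inherits(params, "ipc_params"))
  dt <- check_uniform_grid(grid)
  n <- length(grid)
  k <- params$p / params$m
  decay <- exp(-k * dt)
  x <- numeric(n)

  if (inherits(arrival, "event_train")) {
    jump <- numeric(n)
    sgn <- ifelse(arrival$sign == "E", 1, -1)
    for (i in seq_len(nrow(arrival))) {
      idx <- round((arrival$onset_s[i] - grid[1]) / dt) + 1
      if (idx >= 1 && idx <= n)
        jump[idx] <- jump[idx] +
          sgn[i] * params$c_loss * arrival$amount_bits[i] / params$m
    }
    x[1] <- x0 + jump[1]
    for (i in seq_len(n - 1L))
      x[i + 1L] <- x[i] * decay + jump[i + 1L]
  } else if (inherits(arrival, "ipc_ts")) {
    if (abs(arrival$dt - dt) > 1e-9 || length(arrival) != n)
      stop("sampled arrival must share the simulation grid", call. = FALSE)
    gain <- params$c_loss / params$m * (1 - decay) / k
    x[1] <- x0
    H <- arrival$values
    for (i in seq_len(n - 1L))
      x[i + 1L] <- x[i] * decay + gain * H[i]
  } else {
    stop("'arrival' must be an event_train or an ipc_ts", call. = FALSE)
  }
  time_series(x, dt = dt, t0 = grid[1])
}

#' Information accounting along a simulated trajectory
#'
#' Recovers the three ledgers of the information conservation law
#' \eqn{c\,I(t) = I_p(t) + I_m(t)}: delivered information `I(t)` (signed
#' cumulative bits of the event train), information taken for processing
#' \eqn{I_p(t) = p \int_0^t x(s)\,ds} (trapezoidal cumulative quadrature),
#' and information held in storage \eqn{I_m(t) = m\,x(t)}. The returned
#' residual `c_loss * I - (I_p + I_m)` should vanish (to quadrature
#' accuracy) for trajectories produced by [simulate_ipc()].
#'
#' @param x activity [time_series()] produced by [simulate_ipc()] with the
#'   same `arrival` and `params`.
#' @param arrival the [event_train()] that drove the simulation.
#' @param params the [ipc_params()] used.
#' @return A list of [time_series()]: `I`, `I_p`, `I_m`, `residual`.
#' @export
information_accounting <- function(x, arrival, params) {
  stopifnot(inherits(x, "ipc_ts"), inherits(arrival, "event_train"),
            inherits(params, "ipc_params"))
  tt <- ts_time(x)
  sgn <- ifelse(arrival$sign == "E", 1, -1)
  I <- numeric(length(tt))
  for (i in seq_len(nrow(arrival))) {
    idx <- round((arrival$onset_s[i] - x$t0) / x$dt) + 1
    if (idx >= 1 && idx <= length(tt))
      I[idx:length(tt)] <- I[idx:length(tt)] + sgn[i] * arrival$amount_bits[i]
  }
  I_m <- params$m * x$values
  I_p <- params$p * pracma::cumtrapz(tt, x$values)[, 1]
  resid <- params$c_loss * I - (I_p + I_m)
  list(I = time_series(I, x$dt, x$t0),
       I_p = time_series(I_p, x$dt, x$t0),
       I_m = time_series(I_m, x$dt, x$t0),
       residual = time_series(resid, x$dt, x$t0))
}

#' Map IPC parameters to the single-region DCM parameterization
#'
#' A single-state dynamic causal model \eqn{\dot x = -\sigma x + \beta e(t)}
#' is algebraically identical to the IPC model with self-connectivity
#' \eqn{\sigma = p/m} (1/s) and input strength \eqn{\beta = c/m} (1/bits).
#'
#' @param params an [ipc_params()] object.
#' @return list with `sigma` and `beta_in`, class `sdcm_params`.
#' @examples
#' sdcm_map(ipc_params(p = 2, m = 4))  # sigma 0.5, beta 0.25
#' @export
sdcm_map <- function(params) {
  stopifnot(inherits(params, "ipc_params"))
  structure(list(sigma = params$p / params$m,
                 beta_in = params$c_loss / params$m),
            class = "sdcm_params")
}

#' Invert the single-region DCM mapping
#'
#' @param sdcm an `sdcm_params` object (fields `sigma`, `beta_in`).
#' @param c_loss retained-information fraction assumed for the region
#'   (must be > 0 for the map to be invertible).
#' @return An [ipc_params()] with `m = c_loss / beta_in`, `p = sigma * m`.
#' @export
sdcm_inverse <- function(sdcm, c_loss = 1) {
  if (c_loss <= 0)
    stop("the mapping is not invertible at c_loss = 0 (all information lost)",
         call. = FALSE)
  if (sdcm$sigma <= 0 || sdcm$beta_in <= 0)
    stop("'sigma' and 'beta_in' must be positive", call. = FALSE)
  m <- c_loss / sdcm$beta_in
  ipc_params(p = sdcm$sigma * m, m = m, c_loss = c_loss)
}
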