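#' Two-state excitatory/inhibitory response parameters
#'
#' The fitted neuronal response family for a single event-related trial:
#' a primary excitatory exponential at stimulus onset, a delayed inhibitory
#' exponential (onset `T0`), and a secondary excitatory exponential (onset
#' `T1`), all sharing the regional decay rate `k = p/m`:
#' \deqn{x(t) = a\,e^{-kt}u(t) + c\,e^{-k(t - 2T)}u(t - T_1)
#'   - b\,e^{-k(t - T)}u(t - T_0),}
#' with `T = T_ref` the sampling period. Following the convention in which
#' the model was stated, `b` and `c_amp` are amplitudes referenced to times
#' `T_ref` and `2 T_ref` even when the onsets `T0`, `T1` differ from those
#' references; [two_state_onset_amplitudes()] converts to onset-referenced
#' amplitudes.
#'
#' @param a primary excitatory amplitude `alpha/m` (>= 0).
#' @param b inhibitory amplitude at reference time `T_ref` (>= 0).
#' @param c_amp secondary excitatory amplitude at `2 T_ref` (>= 0).
#' @param k decay rate `p/m` in 1/s (> 0).
#' @param T0 inhibitory onset in s (>= 0).
#' @param T1 secondary excitatory onset in s (>= T0).
#' @param T_ref reference sampling period in s (default 2.5, the TR).
#' @return object of class `two_state_params`.
#' @examples
#' ts2 <- two_state_params(a = 1, b = 0.6, c_amp = 0.2, k = 0.8,
#'                         T0 = 2, T1 = 5)
#' @export
two_state_params <- function(a, b = 0, c_amp = 0, k, T0 = 0, T1 = T0,
                             T_ref = 2.5) {
  if (a < 0 || b < 0 || c_amp < 0)
    stop("amplitudes 'a', 'b', 'c_amp' must be >= 0", call. = FALSE)
  if (k <= 0) stop("'k' must be a positive rate (1/s)", call. = FALSE)
  if (T0 < 0 || T1 < 0)
    stop("onsets must be >= 0 s", call. = FALSE)
  if (T1 < T0)
    stop("'T1' must not precede 'T0' (inhibition precedes the secondary excitation)",
         call. = FALSE)
  structure(list(a = a, b = b, c_amp = c_amp, k = k, T0 = T0, T1 = T1,
                 T_ref = T_ref),
            class = "two_state_params")
}

#' @export
print.two_state_params <- function(x, ...) {
  cat(sprintf(
    "<two_state_params> a = %.4g, b = %.4g, c = %.4g, k = %.4g /s (T_c = %.4g s), T0 = %.2f s, T1 = %.2f s\n",
    x$a, x$b, x$c_amp, x$k, 1 / x$k, x$T0, x$T1))
  invisible(x)
}

#' Evaluate the two-state response on a grid
#'
#' @param params a [two_state_params()] object.
#' @param grid uniform time grid in seconds.
#' @return A [time_series()] of `x(t)`.
#' @export
two_state_response <- function(params, grid) {
  stopifnot(inherits(params, "two_state_params"))
  dt <- check_uniform_grid(grid)
  time_series(two_state_eval(params, grid), dt = dt, t0 = grid[1])
}

# bare numeric evaluation, shared with the fitting code
two_state_eval <- function(p, t) {
  v <- ifelse(t >= 0, p$a * exp(-p$k * pmax(t, 0)), 0)
  if (p$b > 0)
    v <- v - ifelse(t >= p$T0,
                    p$b * exp(-p$k * (t - p$T_ref)), 0)
  if (p$c_amp > 0)
    v <- v + ifelse(t >= p$T1,
                    p$c_amp * exp(-p$k * (t - 2 * p$T_ref)), 0)
  v
}

#' Onset-referenced amplitudes of the two-state response
#'
#' Re-expresses the reference-time amplitudes `b` (at `T_ref`) and `c_amp`
#' (at `2 T_ref`) as the component amplitudes at their actual onsets `T0`
#' and `T1`, i.e. the jump sizes `beta/m` and `alpha_1/m` of the underlying
#' event train.
#'
#' @param params a [two_state_params()] object.
#' @return named numeric vector with `b_onset` and `c_onset`.
#' @export
two_state_onset_amplitudes <- function(params) {
  stopifnot(inherits(params, "two_state_params"))
  c(b_onset = params$b * exp(-params$k * (params$T0 - params$T_ref)),
    c_onset = params$c_amp * exp(-params$k * (params$T1 - 2 * params$T_ref)))
}

#' Event train equivalent to a two-state response
#'
#' Converts the fitted response family into the impulse deliveries that
#' generate it under the IPC model with storage capacity `m`: an excitatory
#' impulse of `a*m` bits at 0, an inhibitory impulse at `T0` and a secondary
#' excitatory impulse at `T1` with the onset-referenced amplitudes.
#'
#' @param params a [two_state_params()] object.
#' @param m storage capacity in bits used to scale activities to bits.
#' @param t_offset shift applied to all onsets (s), e.g. a trial onset time.
#' @return An [event_train()].
#' @export
two_state_events <- function(params, m = 1, t_offset = 0) {
  amp <- two_state_onset_amplitudes(params)
  exc <- data.frame(time = t_offset, amount = params$a * m)
  if (amp[["c_onset"]] > 0)
    exc <- rbind(exc, data.frame(time = t_offset + params$T1,
                                 amount = amp[["c_onset"]] * m))
  inh <- NULL
  if (amp[["b_onset"]] > 0)
    inh <- data.frame(time = t_offset + params$T0,
                      amount = amp[["b_onset"]] * m)
  event_train(excitatory = exc[order(exc$time), , drop = FALSE],
              inhibitory = inh)
}
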