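#' Causal convolution of neuronal activity with a hemodynamic kernel
#'
#' Discrete Riemann approximation of the continuous convolution
#' \eqn{y(t) = \int_0^t x(\tau) h(t - \tau)\, d\tau}: the full discrete
#' convolution scaled by `dt`, truncated to the length of `x` (the kernel
#' tail beyond the signal end is discarded). Both series must share the
#' sampling step; signals are causal, so zero-padding before `t = 0` is
#' implicit.
#'
#' @param x neuronal-activity [time_series()].
#' @param h kernel [time_series()] on the same `dt` (e.g. [hrf_kernel()]).
#' @return A [time_series()] of the BOLD prediction, same grid as `x`.
#' @examples
#' g <- seq(0, 32, by = 0.1)
#' x <- step_response(1, 0.5, g)
#' y <- convolve_bold(x, hrf_kernel(hrf_params(), g))
#' @export
convolve_bold <- function(x, h) {
  stopifnot(inherits(x, "ipc_ts"), inherits(h, "ipc_ts"))
  if (abs(x$dt - h$dt) > 1e-9)
    stop("'x' and 'h' must share the sampling step dt", call. = FALSE)
  n <- length(x$values)
  full <- stats::convolve(x$values, rev(h$values), type = "open")
  time_series(full[seq_len(n)] * x$dt, dt = x$dt, t0 = x$t0)
}

#' Measurement-noise model for sampled BOLD
#'
#' @param kind one of `"none"`, `"white"` (i.i.d. Gaussian) or `"ar1"`
#'   (stationary AR(1) Gaussian, marginal SD `sigma`).
#' @param sigma noise standard deviation in BOLD units (>= 0).
#' @param rho AR(1) coefficient, |rho| < 1 (ignored unless `kind = "ar1"`).
#' @param seed integer seed; `NULL` draws from the session RNG stream.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "white", "ar1"), sigma = 0,
                        rho = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  if (abs(rho) >= 1) stop("'rho' must satisfy |rho| < 1", call. = FALSE)
  structure(list(kind = kind, sigma = sigma, rho = rho, seed = seed),
            class = "noise_model")
}

# draw a noise vector; uses a local RNG state when a seed is given so the
# caller's stream is untouched
draw_noise <- function(noise, n) {
  if (noise$kind == "none" || noise$sigma == 0) return(numeric(n))
  gen <- function() {
    if (noise$kind == "white") {
      stats::rnorm(n, sd = noise$sigma)
    } else {
      innov_sd <- noise$sigma * sqrt(1 - noise$rho^2)
      as.numeric(stats::arima.sim(list(ar = noise$rho), n = n,
                                  sd = innov_sd))
    }
  }
  if (is.null(noise$seed)) return(gen())
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(noise$seed)
  gen()
}

#' Sample a fine-grid BOLD series at the scanner TR and add noise
#'
#' Takes every `tr/dt`-th sample starting at the first grid point and adds
#' measurement noise according to the [noise_model()]. With a fixed seed the
#' output is reproducible.
#'
#' @param y fine-grid BOLD [time_series()].
#' @param tr repetition time in seconds; must be an integer multiple of
#'   `y$dt`.
#' @param noise a [noise_model()] (default: no noise).
#' @return A [time_series()] sampled at `dt = tr` (a "sampled BOLD" series).
#' @export
sample_and_noise <- function(y, tr, noise = noise_model()) {
  stopifnot(inherits(y, "ipc_ts"), inherits(noise, "noise_model"))
  ratio <- tr / y$dt
  if (abs(ratio - round(ratio)) > 1e-8)
    stop("'tr' must be an integer multiple of the fine-grid dt",
         call. = FALSE)
  ratio <- round(ratio)
  idx <- seq(1L, length(y$values), by = ratio)
  v <- y$values[idx] + draw_noise(noise, length(idx))
  time_series(v, dt = tr, t0 = y$t0)
}
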