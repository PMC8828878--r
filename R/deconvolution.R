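#' Deconvolution configuration
#'
#' @param lambda_ridge Tikhonov weight (>= 0; default 0, plain least
#'   squares). On ill-conditioning (condition number of the normal
#'   equations above `cond_limit`) a fallback ridge of
#'   `1e-6 * trace(C'C)/n` is applied with a message.
#' @param support_s assumed support of the neuronal response (s); multiple
#'   of the data TR. The estimate is returned at TR resolution on
#'   `[0, support_s]`.
#' @param fine_dt fine grid step used to represent the continuous
#'   convolution and for spline upsampling (s).
#' @param cond_limit condition-number threshold triggering the fallback.
#' @return list of class `deconv_config`.
#' @export
deconv_config <- function(lambda_ridge = 0, support_s = 15, fine_dt = 0.1,
                          cond_limit = 1e10) {
  if (lambda_ridge < 0) stop("'lambda_ridge' must be >= 0", call. = FALSE)
  structure(list(lambda_ridge = lambda_ridge, support_s = support_s,
                 fine_dt = fine_dt, cond_limit = cond_limit),
            class = "deconv_config")
}

# Linear operator mapping neuronal-response values at TR knots on
# [0, support_s] to BOLD samples at the TR. The knot vector is carried to
# the fine grid by natural cubic spline interpolation (zero beyond the
# support), convolved with the HRF at fine_dt and decimated back to the
# TR — i.e. exactly the discretization used by the forward simulator, so a
# noise-free round trip is exact up to the spline representation of x.
build_conv_operator <- function(hrf, tr, n_y, support_s, fine_dt) {
  n_k <- round(support_s / tr) + 1L
  knots_t <- (0:(n_k - 1L)) * tr
  t_end <- (n_y - 1L) * tr
  fine_t <- seq(0, t_end, by = fine_dt)
  h <- hrf_kernel(hrf, seq(0, 32, by = fine_dt))
  ratio <- round(tr / fine_dt)
  C <- matrix(0, n_y, n_k)
  for (j in seq_len(n_k)) {
    e <- numeric(n_k); e[j] <- 1
    xf <- numeric(length(fine_t))
    inside <- fine_t <= support_s + 1e-9
    xf[inside] <- spline_upsample(time_series(e, dt = tr, t0 = 0),
                                  fine_dt = fine_dt)$values[
                                    seq_len(sum(inside))]
    yf <- convolve_bold(time_series(xf, dt = fine_dt, t0 = 0), h)
    C[, j] <- yf$values[seq(1L, length(yf$values), by = ratio)][seq_len(n_y)]
  }
  list(C = C, knots_t = knots_t)
}

#' Least-squares hemodynamic deconvolution
#'
#' Estimates the neuronal response function from a sampled BOLD impulse
#' response by solving the Tikhonov-regularized least-squares problem
#' \deqn{\min_x \|y - C x\|^2 + \lambda \|x\|^2,}
#' where `C` is the causal convolution operator of the chosen HRF acting on
#' the TR-resolution response (knots on `[0, support_s]`, carried through
#' the continuous convolution on a fine grid). With `lambda = 0` and enough
#' BOLD samples this is plain least squares; rank-deficient systems fall
#' back to a small automatic ridge.
#'
#' @param y sampled BOLD [time_series()] at the TR (e.g. a trial-averaged
#'   impulse response from [trial_average()]).
#' @param hrf an [hrf_params()] object.
#' @param cfg a [deconv_config()].
#' @return A [time_series()] `x_est` at TR resolution on `[0, support_s]`,
#'   with attributes `lambda_used` and `condition_number`.
#' @export
deconvolve_ls <- function(y, hrf, cfg = deconv_config()) {
  stopifnot(inherits(y, "ipc_ts"), inherits(hrf, "hrf_params"),
            inherits(cfg, "deconv_config"))
  tr <- y$dt
  if (abs(cfg$support_s / tr - round(cfg$support_s / tr)) > 1e-8)
    stop("'support_s' must be a multiple of the data TR", call. = FALSE)
  n_y <- length(y$values)
  if (n_y < round(cfg$support_s / tr))
    stop("BOLD series shorter than the assumed response support",
         call. = FALSE)
  op <- build_conv_operator(hrf, tr, n_y, cfg$support_s, cfg$fine_dt)
  C <- op$C
  CtC <- crossprod(C)
  n <- ncol(C)
  cond <- tryCatch(kappa(CtC, exact = TRUE), error = function(e) Inf)
  lambda <- cfg$lambda_ridge
  if (lambda == 0 && cond > cfg$cond_limit) {
    lambda <- 1e-6 * sum(diag(CtC)) / n
    message(sprintf(
      "deconvolve_ls: normal equations ill-conditioned (kappa = %.3g); using ridge lambda = %.3g",
      cond, lambda))
  }
  x <- tryCatch(
    solve(CtC + lambda * diag(n), crossprod(C, y$values)),
    error = function(e)
      stop("singular normal equations; set lambda_ridge > 0", call. = FALSE))
  out <- time_series(as.numeric(x), dt = tr, t0 = 0)
  attr(out, "lambda_used") <- lambda
  attr(out, "condition_number") <- cond
  out
}

#' Cubic-spline upsampling of a TR-resolution series
#'
#' Natural cubic spline through the knots, evaluated on a fine grid; exact
#' at the knots.
#'
#' @param x [time_series()] at coarse resolution with at least 4 knots.
#' @param fine_dt target step in seconds.
#' @return A [time_series()] at `fine_dt` spanning the same interval.
#' @export
spline_upsample <- function(x, fine_dt = 0.1) {
  stopifnot(inherits(x, "ipc_ts"))
  if (length(x$values) < 4L)
    stop("spline upsampling needs at least 4 knots", call. = FALSE)
  tt <- ts_time(x)
  fine_t <- seq(tt[1], tt[length(tt)], by = fine_dt)
  sp <- stats::spline(tt, x$values, xout = fine_t, method = "natural")
  time_series(sp$y, dt = fine_dt, t0 = tt[1])
}
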