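#' Uniformly sampled time series
#'
#' Lightweight container for a real-valued signal sampled on a uniform time
#' grid, the common currency of this package: neuronal activity `x(t)`,
#' hemodynamic kernels `h(t)`, and BOLD signals `y(t)` all travel as
#' `ipc_ts` objects.
#'
#' @param values numeric vector of samples.
#' @param dt sampling step in seconds (> 0).
#' @param t0 time of the first sample in seconds (default 0).
#' @return An object of class `ipc_ts` with fields `values`, `dt`, `t0`.
#' @examples
#' ts <- time_series(exp(-seq(0, 5, by = 0.1)), dt = 0.1)
#' head(ts_time(ts))
#' @export
time_series <- function(values, dt, t0 = 0) {
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stop("'values' must be finite numeric", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive number", call. = FALSE)
  structure(list(values = as.numeric(values), dt = as.numeric(dt),
                 t0 = as.numeric(t0)),
            class = "ipc_ts")
}

#' Time axis of a time series
#' @param ts an `ipc_ts` object.
#' @return numeric vector of sample times in seconds.
#' @export
ts_time <- function(ts) {
  stopifnot(inherits(ts, "ipc_ts"))
  ts$t0 + ts$dt * (seq_along(ts$values) - 1L)
}

#' @export
print.ipc_ts <- function(x, ...) {
  cat(sprintf("<ipc_ts> %d samples, dt = %g s, t0 = %g s, range [%g, %g]\n",
              length(x$values), x$dt, x$t0,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.ipc_ts <- function(x, ...) {
  data.frame(time_s = ts_time(x), value = x$values)
}

#' @export
length.ipc_ts <- function(x) length(x$values)

# uniform grid constructor used throughout: seq(0, t_end, by = dt)
ts_grid <- function(t_end, dt, t0 = 0) seq(t0, t_end, by = dt)

# check two series share a grid
same_grid <- function(a, b, tol = 1e-9) {
  abs(a$dt - b$dt) < tol && abs(a$t0 - b$t0) < tol &&
    length(a$values) == length(b$values)
}

check_uniform_grid <- function(grid) {
  if (length(grid) < 2L)
    stop("grid must contain at least two points", call. = FALSE)
  d <- diff(grid)
  if (any(d <= 0) || max(abs(d - d[1])) > 1e-9 * max(d[1], 1))
    stop("grid must be uniformly spaced and increasing", call. = FALSE)
  d[1]
}
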