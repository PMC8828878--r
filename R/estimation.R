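# Fitting the two-state excitation/inhibition response and deriving the
# relative capacity parameters.
#
# The response family is linear in its three amplitudes once the decay
# rate k and the onsets (T0, T1) are fixed, so both fitting objectives
# (activity domain and BOLD domain) profile the amplitudes out by
# non-negative least squares over the full onset grid, leaving a 1-D
# search in k. The onset-pair scan is fully vectorized: every Gram entry
# over the grid is precomputed, and the 7 candidate support sets of the
# 3-variable NNLS are solved in closed form by broadcasting.

# minimum of -2 g'c + c'Gc over c >= 0 for every onset pair at once.
# Scalars: G11, g1. Vectors over the T0 grid: G12i (signed), G22i, g2i
# (signed). Vectors over the T1 grid: G13j, G33j, g3j. Matrix (i x j):
# G23ij (signed). valid: logical matrix of admissible pairs (T0 <= T1).
# Returns the q matrix minimized over supports (Inf where invalid).
scan_pairs_q <- function(G11, g1, G12i, G22i, g2i, G13j, G33j, g3j,
                         G23ij, valid) {
  n0 <- length(G22i)
  n1 <- length(G33j)
  R <- function(v) matrix(v, n0, n1)              # broadcast over rows (i)
  C <- function(v) matrix(v, n0, n1, byrow = TRUE) # broadcast over cols (j)
  q <- matrix(0, n0, n1)                           # empty support

  keep <- function(qs, feas) {
    qs[!feas | !is.finite(qs)] <- Inf
    q <<- pmin(q, qs)
  }

  # single-variable supports
  if (G11 > 0 && g1 / G11 >= 0) q[] <- pmin(q, -g1^2 / G11)
  c2 <- g2i / G22i
  keep(R(-g2i^2 / G22i), R(c2 >= 0 & G22i > 0))
  c3 <- g3j / G33j
  keep(C(-g3j^2 / G33j), C(c3 >= 0 & G33j > 0))

  # two-variable supports; determinants are compared to the product of
  # the diagonal entries so near-collinear column pairs (e.g. the two
  # delayed exponentials at T0 == T1, which are exactly proportional) are
  # excluded rather than amplified into spurious minima — the cone they
  # span is already covered by the single-variable supports
  rel_eps <- 1e-10
  d12 <- G11 * G22i - G12i^2
  a12 <- (g1 * G22i - g2i * G12i) / d12
  b12 <- (g2i * G11 - g1 * G12i) / d12
  keep(R(-(a12 * g1 + b12 * g2i)),
       R(d12 > rel_eps * G11 * G22i & a12 >= 0 & b12 >= 0))
  d13 <- G11 * G33j - G13j^2
  a13 <- (g1 * G33j - g3j * G13j) / d13
  b13 <- (g3j * G11 - g1 * G13j) / d13
  keep(C(-(a13 * g1 + b13 * g3j)),
       C(d13 > rel_eps * G11 * G33j & a13 >= 0 & b13 >= 0))
  diag23 <- outer(G22i, G33j)
  d23 <- diag23 - G23ij^2
  a23 <- (R(g2i) * C(G33j) - C(g3j) * G23ij) / d23
  b23 <- (C(g3j) * R(G22i) - R(g2i) * G23ij) / d23
  keep(-(a23 * R(g2i) + b23 * C(g3j)),
       d23 > rel_eps * diag23 & a23 >= 0 & b23 >= 0)

  # full support via cofactor expansion
  M11 <- d23
  M12 <- R(G12i) * C(G33j) - C(G13j) * G23ij
  M13 <- R(G12i) * G23ij - R(G22i) * C(G13j)
  det3 <- G11 * M11 - R(G12i) * M12 + C(G13j) * M13
  c1f <- (g1 * M11 - R(g2i) * M12 + C(g3j) * M13) / det3
  c2f <- (-g1 * M12 + R(g2i) * (G11 * C(G33j) - C(G13j)^2) -
            C(g3j) * (G11 * G23ij - R(G12i) * C(G13j))) / det3
  c3f <- (g1 * M13 - R(g2i) * (G11 * G23ij - R(G12i) * C(G13j)) +
            C(g3j) * (G11 * R(G22i) - R(G12i)^2)) / det3
  keep(-(c1f * g1 + c2f * R(g2i) + c3f * C(g3j)),
       det3 > rel_eps * G11 * diag23 & c1f >= 0 & c2f >= 0 & c3f >= 0)

  q[!valid] <- Inf
  q
}

# pick the minimizing pair, breaking ties toward the earliest (T0, T1)
scan_best_pair <- function(q, T0_grid, T1_grid) {
  qmin <- min(q)
  hit <- which(q <= qmin + 1e-13, arr.ind = TRUE)
  ord <- order(T0_grid[hit[, 1]], T1_grid[hit[, 2]])
  i <- hit[ord[1L], 1L]
  j <- hit[ord[1L], 2L]
  list(q = q[i, j], T0 = T0_grid[i], T1 = T1_grid[j])
}

# exact non-negative LS for one 3x3 system (used to recover the
# amplitudes at the winning grid point)
nnls3 <- function(G, g) {
  best_q <- 0
  cf <- c(0, 0, 0)
  try_set <- function(v) {
    q <- -2 * sum(v * g) + as.numeric(v %*% G %*% v)
    if (q < best_q - 1e-15) {
      best_q <<- q
      cf <<- v
    }
  }
  for (mask in 1:7) {
    idx <- which(bitwAnd(mask, c(1L, 2L, 4L)) > 0)
    sol <- tryCatch(solve(G[idx, idx, drop = FALSE], g[idx]),
                    error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol)) || any(sol < 0)) next
    v <- numeric(3)
    v[idx] <- sol
    try_set(v)
  }
  list(coef = cf, q = best_q)
}

# basis matrix of the two-state family at fixed (k, T0, T1); columns
# correspond to the non-negative coefficients (a, b, c_amp)
two_state_basis <- function(t, k, T0, T1, T_ref) {
  cbind(exp(-k * pmax(t, 0)) * (t >= 0),
        -exp(-k * (t - T_ref)) * (t >= T0),
        exp(-k * (t - 2 * T_ref)) * (t >= T1))
}

# Tikhonov weight on the delayed (inhibitory and secondary excitatory)
# amplitudes, relative to the energy of the primary column. The profiled
# objective carries deep near-degenerate dips in which extreme delayed
# amplitudes compensate a wrong decay rate; the penalty suppresses those
# pathological fits. AMP_RIDGE_FLOOR is the numerical floor used on the
# first pass; the search then adapts the weight to the measured residual
# level (see k_profile_search), so noise-free fits stay exact while noisy
# fits are stabilized in proportion to the noise.
AMP_RIDGE_FLOOR <- 1e-6

# penalized NNLS at one grid point; the reported SSR is unpenalized
ridge_nnls3 <- function(G, g, offset, ridge) {
  Gp <- G
  pen <- ridge * G[1, 1]
  Gp[2, 2] <- Gp[2, 2] + pen
  Gp[3, 3] <- Gp[3, 3] + pen
  fit <- nnls3(Gp, g)
  cf <- fit$coef
  q <- -2 * sum(cf * g) + as.numeric(cf %*% G %*% cf)
  list(ssr = offset + q, coef = cf)
}

ssr_coef_at <- function(t, x, xx, k, T0, T1, T_ref,
                        ridge = AMP_RIDGE_FLOOR) {
  B <- two_state_basis(t, k, T0, T1, T_ref)
  ridge_nnls3(crossprod(B), crossprod(B, x)[, 1], xx, ridge)
}

# --- activity-domain objective --------------------------------------------
# Onset truncation makes every Gram entry a suffix sum of a fixed product
# vector, so the whole onset grid is scanned in O(n) precomputation.

x_scan_env <- function(x_est, T_ref, onset_step) {
  t <- ts_time(x_est)
  dt <- x_est$dt
  if (abs(t[1]) > 1e-9)
    stop("x_est must start at t = 0", call. = FALSE)
  if (abs(onset_step / dt - round(onset_step / dt)) > 1e-8)
    stop("'onset_step' must be a multiple of the x_est grid step",
         call. = FALSE)
  T0_grid <- seq(0, 2 * T_ref, by = onset_step)
  T1_grid <- seq(T_ref, 4 * T_ref, by = onset_step)
  list(t = t, x = x_est$values, xx = sum(x_est$values^2), dt = dt,
       T_ref = T_ref, T0_grid = T0_grid, T1_grid = T1_grid,
       i0 = round(T0_grid / dt) + 1L, i1 = round(T1_grid / dt) + 1L,
       valid = outer(T0_grid, T1_grid, "<="))
}

x_scan <- function(env, k, ridge = AMP_RIDGE_FLOOR) {
  suffix <- function(v) rev(cumsum(rev(v)))
  e1 <- exp(-k * env$t)
  e2 <- exp(-k * (env$t - env$T_ref))
  e3 <- exp(-k * (env$t - 2 * env$T_ref))
  x <- env$x
  i0 <- env$i0
  i1 <- env$i1
  G11 <- sum(e1 * e1)
  q <- scan_pairs_q(
    G11 = G11, g1 = sum(e1 * x),
    G12i = -suffix(e1 * e2)[i0],
    G22i = suffix(e2 * e2)[i0] + ridge * G11,
    g2i = -suffix(e2 * x)[i0],
    G13j = suffix(e1 * e3)[i1],
    G33j = suffix(e3 * e3)[i1] + ridge * G11,
    g3j = suffix(e3 * x)[i1],
    G23ij = matrix(-suffix(e2 * e3)[i1], length(i0), length(i1),
                   byrow = TRUE),
    valid = env$valid)
  b <- scan_best_pair(q, env$T0_grid, env$T1_grid)
  list(ssr = env$xx + b$q, T0 = b$T0, T1 = b$T1)
}

# --- BOLD-domain objective -------------------------------------------------
# The three response components share the decay rate, so their convolved
# shapes are time shifts (and scalings) of a single convolved exponential:
# one convolution per k serves the whole onset grid.

bold_basis_env <- function(y_obs, hrf, T_ref, fine_dt, onset_step = 0.1) {
  tr <- y_obs$dt
  n <- length(y_obs$values)
  ratio <- round(tr / fine_dt)
  fine_t <- seq(0, (n - 1L) * tr, by = fine_dt)
  h <- hrf_kernel(hrf, seq(0, 32, by = fine_dt))
  idx <- seq(1L, length(fine_t), by = ratio)
  T0_grid <- seq(0, 2 * T_ref, by = onset_step)
  T1_grid <- seq(T_ref, 4 * T_ref, by = onset_step)
  # precomputed shifted-sample indices: entry (i, j) addresses
  # c_base[t_i - T_j]; non-positive indices mean "before the onset"
  IDX0 <- outer(idx, as.integer(round(T0_grid / fine_dt)), "-")
  IDX1 <- outer(idx, as.integer(round(T1_grid / fine_dt)), "-")
  mask0 <- IDX0 >= 1L
  mask1 <- IDX1 >= 1L
  IDX0[!mask0] <- 1L
  IDX1[!mask1] <- 1L
  list(tr = tr, n = n, fine_t = fine_t, h = h, idx = idx,
       y = y_obs$values, yy = sum(y_obs$values^2), T_ref = T_ref,
       fine_dt = fine_dt, T0_grid = T0_grid, T1_grid = T1_grid,
       IDX0 = IDX0, IDX1 = IDX1, mask0 = mask0, mask1 = mask1,
       valid = outer(T0_grid, T1_grid, "<="))
}

shift_zero <- function(v, by) {
  if (by == 0L) return(v)
  c(numeric(by), v[seq_len(length(v) - by)])
}

bold_scan <- function(env, k, ridge = AMP_RIDGE_FLOOR) {
  c_base <- convolve_bold(
    time_series(exp(-k * env$fine_t), dt = env$fine_dt, t0 = 0),
    env$h)$values
  s0 <- c_base[env$idx]
  M0 <- matrix(c_base[env$IDX0], env$n) * env$mask0
  M1 <- matrix(c_base[env$IDX1], env$n) * env$mask1
  sc0 <- exp(-k * (env$T0_grid - env$T_ref))      # scale of the b column
  sc1 <- exp(-k * (env$T1_grid - 2 * env$T_ref))  # scale of the c column
  G11 <- sum(s0 * s0)
  q <- scan_pairs_q(
    G11 = G11, g1 = sum(s0 * env$y),
    G12i = -sc0 * crossprod(M0, s0)[, 1],
    G22i = sc0^2 * colSums(M0^2) + ridge * G11,
    g2i = -sc0 * crossprod(M0, env$y)[, 1],
    G13j = sc1 * crossprod(M1, s0)[, 1],
    G33j = sc1^2 * colSums(M1^2) + ridge * G11,
    g3j = sc1 * crossprod(M1, env$y)[, 1],
    G23ij = -(outer(sc0, sc1) * crossprod(M0, M1)),
    valid = env$valid)
  b <- scan_best_pair(q, env$T0_grid, env$T1_grid)
  list(ssr = env$yy + b$q, T0 = b$T0, T1 = b$T1)
}

# recover the amplitudes of a BOLD-domain fit at fixed (k, T0, T1)
bold_coef_at <- function(env, k, T0, T1,
                         ridge = AMP_RIDGE_FLOOR) {
  c_base <- convolve_bold(
    time_series(exp(-k * env$fine_t), dt = env$fine_dt, t0 = 0),
    env$h)$values
  samp <- function(T) shift_zero(c_base, round(T / env$fine_dt))[env$idx]
  B <- cbind(c_base[env$idx],
             -exp(-k * (T0 - env$T_ref)) * samp(T0),
             exp(-k * (T1 - 2 * env$T_ref)) * samp(T1))
  ridge_nnls3(crossprod(B), crossprod(B, env$y)[, 1], env$yy,
              ridge)
}

# --- shared 1-D search in the decay rate -----------------------------------
# The pooled profiled SSR is a shallow valley that can carry several deep,
# narrow dips (near-degenerate alternative fits in which the delayed
# components compensate a wrong decay rate). The search proceeds in three
# stages: a global log-spaced sweep, a dense scan of the valley region
# (fixed evaluation budget, so the step adapts to the valley width), and
# local refinement of the leading dips by bracket zoom plus golden
# section.
k_profile_search <- function(scan_fns, k_bounds, yy_total,
                             n_sweep = 40L, n_dense = 240L, n_dips = 4L) {
  run_search <- function(ridge, n_dense_r, n_dips_r) {
    pooled <- function(k)
      sum(vapply(scan_fns, function(f) f(k, ridge)$ssr, 0))

    # stage 1: global sweep
    k_grid <- exp(seq(log(k_bounds[1]), log(k_bounds[2]),
                      length.out = n_sweep))
    sweep <- vapply(k_grid, pooled, 0)
    smin <- min(sweep)

    # stage 2: dense scan of the valley (bounding interval of all sweep
    # points within 50x of the minimum, padded by one sweep step)
    in_valley <- which(sweep <= 50 * smin + 1e-300)
    lo <- k_grid[max(1L, min(in_valley) - 1L)]
    hi <- k_grid[min(n_sweep, max(in_valley) + 1L)]
    kd <- exp(seq(log(lo), log(hi), length.out = n_dense_r))
    vd <- vapply(kd, pooled, 0)

    # stage 3: refine the best local minima of the dense scan
    nd <- n_dense_r
    is_min <- c(vd[1] <= vd[2],
                vd[-c(1, nd)] <= vd[-c(nd - 1, nd)] &
                  vd[-c(1, nd)] <= vd[-c(1, 2)],
                vd[nd] <= vd[nd - 1])
    cand <- which(is_min)[order(vd[is_min])]
    cand <- cand[seq_len(min(n_dips_r, length(cand)))]
    refine_dip <- function(lo, hi) {
      kg <- NULL
      jb <- 1L
      vals <- NULL
      for (zoom in 1:2) {
        kg <- exp(seq(log(lo), log(hi), length.out = 7L))
        vals <- vapply(kg, pooled, 0)
        jb <- which.min(vals)
        lo <- kg[max(1L, jb - 1L)]
        hi <- kg[min(7L, jb + 1L)]
      }
      op <- stats::optimize(pooled, interval = c(lo, hi), tol = 1e-12)
      if (vals[jb] < op$objective) list(k = kg[jb], ssr = vals[jb])
      else list(k = op$minimum, ssr = op$objective)
    }
    best_k <- kd[which.min(vd)]
    best_ssr <- min(vd)
    for (j in cand) {
      r <- refine_dip(kd[max(1L, j - 1L)], kd[min(nd, j + 1L)])
      if (r$ssr < best_ssr) {
        best_ssr <- r$ssr
        best_k <- r$k
      }
    }
    list(k = best_k, ssr = best_ssr)
  }

  # first pass at the numerical floor; its minimized residual estimates
  # the noise energy, to which the amplitude ridge of a second pass is
  # scaled. Noise-free data keeps the floor (single pass, no penalty
  # beyond numerics); noisy data gets a penalty proportional to the noise
  # level, which suppresses the degenerate wrong-k dips that pure least
  # squares would chase. The second pass can be lighter: the ridge
  # flattens the dips it exists to reject.
  r1 <- run_search(AMP_RIDGE_FLOOR, n_dense, n_dips)
  ridge <- max(AMP_RIDGE_FLOOR, 3 * r1$ssr / yy_total)
  if (ridge <= 10 * AMP_RIDGE_FLOOR) {
    r1$ridge <- AMP_RIDGE_FLOOR
    return(r1)
  }
  r2 <- run_search(ridge, max(60L, n_dense %/% 4L), 2L)
  r2$ridge <- ridge
  r2
}

#' Fit the two-state excitation/inhibition response
#'
#' Minimizes the sum of squared residuals between the (upsampled)
#' deconvolved neuronal response `x_est` and the two-state family
#' \deqn{x(t) = a\,e^{-kt}u(t) + c\,e^{-k(t-2T)}u(t-T_1)
#'   - b\,e^{-k(t-T)}u(t-T_0).}
#' Onsets are searched exhaustively on an `onset_step` grid — `T0` over
#' `[0, 2 T_ref]`, `T1` over `[T_ref, 4 T_ref]` with `T0 <= T1` — with the
#' three amplitudes profiled out by non-negative least squares at every
#' pair, and the decay rate optimized by a dense log-spaced sweep plus
#' golden-section polish within `k_bounds`. Ties are broken toward the
#' earliest `(T0, T1)`.
#'
#' When the observed BOLD and the HRF are supplied, a refinement stage
#' re-estimates all parameters by minimizing the BOLD-domain prediction
#' error \eqn{\|y - (x_{model} * h)\downarrow\|^2} (the model-accuracy
#' criterion itself), seeded by the activity-domain solution and searched
#' the same way. This removes the bias that TR-resolution deconvolution
#' and spline interpolation imprint on the activity-domain fit of fast
#' responses; for noise-free data generated by the model family the
#' refined fit is exact.
#'
#' @param x_est fine-grid neuronal response [time_series()] starting at
#'   t = 0 (from [spline_upsample()]).
#' @param T_ref reference sampling period in s (default 2.5).
#' @param k_bounds search bounds for the decay rate `k = p/m` (1/s).
#' @param onset_step onset grid resolution in s (multiple of the `x_est`
#'   step).
#' @param y_obs optional observed sampled BOLD [time_series()] at the TR
#'   (e.g. the trial-averaged impulse response); enables the BOLD-domain
#'   refinement stage.
#' @param hrf optional [hrf_params()] used by the refinement stage.
#' @param fine_dt fine grid step for the refinement convolution (s).
#' @return A [two_state_params()] with attributes `ssr` (residual sum of
#'   squares in the domain last fitted) and `diagnostics` (search size,
#'   converged flag, refinement stage used).
#' @export
fit_two_state <- function(x_est, T_ref = 2.5, k_bounds = c(0.01, 10),
                          onset_step = 0.1, y_obs = NULL, hrf = NULL,
                          fine_dt = 0.1) {
  stopifnot(inherits(x_est, "ipc_ts"))
  if (max(abs(x_est$values)) < 1e-12)
    stop("degenerate input: x_est is identically zero", call. = FALSE)
  env <- x_scan_env(x_est, T_ref, onset_step)
  refine <- !is.null(y_obs) && !is.null(hrf)
  k_hat <- NA_real_
  T0_hat <- NA_real_
  T1_hat <- NA_real_
  coef_hat <- rep(NA_real_, 3)
  ssr_hat <- NA_real_
  if (!refine) {
    ks <- k_profile_search(list(function(k, r) x_scan(env, k, r)),
                           k_bounds, yy_total = env$xx)
    sc <- x_scan(env, ks$k, ks$ridge)
    fin <- ssr_coef_at(env$t, env$x, env$xx, ks$k, sc$T0, sc$T1, T_ref,
                       ridge = ks$ridge)
    k_hat <- ks$k
    T0_hat <- sc$T0
    T1_hat <- sc$T1
    coef_hat <- fin$coef
    ssr_hat <- fin$ssr
  }

  if (refine) {
    stopifnot(inherits(y_obs, "ipc_ts"), inherits(hrf, "hrf_params"))
    benv <- bold_basis_env(y_obs, hrf, T_ref, fine_dt, onset_step)
    bs <- k_profile_search(list(function(k, r) bold_scan(benv, k, r)),
                           k_bounds, yy_total = benv$yy)
    bsc <- bold_scan(benv, bs$k, bs$ridge)
    bfin <- bold_coef_at(benv, bs$k, bsc$T0, bsc$T1, ridge = bs$ridge)
    k_hat <- bs$k
    T0_hat <- bsc$T0
    T1_hat <- bsc$T1
    coef_hat <- bfin$coef
    ssr_hat <- bfin$ssr
  }

  out <- two_state_params(a = coef_hat[1], b = coef_hat[2],
                          c_amp = coef_hat[3], k = k_hat,
                          T0 = T0_hat, T1 = T1_hat, T_ref = T_ref)
  attr(out, "ssr") <- ssr_hat
  attr(out, "diagnostics") <- list(
    onset_pairs = sum(env$valid), converged = is.finite(ssr_hat),
    bold_refined = refine)
  out
}

#' Fit several conditions with a shared decay rate
#'
#' Within one group the processing capacity `p` (and storage `m`) are
#' assumed constant across task conditions, so the Congruent and
#' Incongruent responses share `k = p/m` while amplitudes and onsets are
#' condition specific. The shared `k` is optimized on the pooled residual
#' sum of squares, with the per-condition onset scan and amplitude
#' profiling nested inside. When per-condition observed BOLD series and
#' the HRF are supplied, the pooled objective is evaluated in the BOLD
#' domain (see [fit_two_state()]).
#'
#' @param x_list named list of fine-grid response [time_series()] (one per
#'   condition).
#' @param T_ref,k_bounds,onset_step as in [fit_two_state()].
#' @param y_list optional named list of observed sampled BOLD series
#'   matching `x_list`; enables BOLD-domain fitting.
#' @param hrf optional [hrf_params()] for the BOLD-domain objective.
#' @param fine_dt fine grid step for the BOLD-domain convolution (s).
#' @return named list of [two_state_params()] (shared `k`), with attribute
#'   `ssr` (pooled).
#' @export
fit_two_state_shared <- function(x_list, T_ref = 2.5,
                                 k_bounds = c(0.01, 10), onset_step = 0.1,
                                 y_list = NULL, hrf = NULL, fine_dt = 0.1) {
  stopifnot(is.list(x_list), length(x_list) >= 1L)
  use_bold <- !is.null(y_list) && !is.null(hrf)
  if (use_bold) {
    stopifnot(is.list(y_list), length(y_list) == length(x_list))
    envs <- lapply(y_list, bold_basis_env, hrf = hrf, T_ref = T_ref,
                   fine_dt = fine_dt, onset_step = onset_step)
    scans <- lapply(envs, function(e) function(k, r) bold_scan(e, k, r))
    yy_total <- sum(vapply(envs, `[[`, 0, "yy"))
  } else {
    envs <- lapply(x_list, x_scan_env, T_ref = T_ref,
                   onset_step = onset_step)
    scans <- lapply(envs, function(e) function(k, r) x_scan(e, k, r))
    yy_total <- sum(vapply(envs, `[[`, 0, "xx"))
  }
  ks <- k_profile_search(scans, k_bounds, yy_total = yy_total)
  fits <- lapply(seq_along(envs), function(i) {
    if (use_bold) {
      sc <- bold_scan(envs[[i]], ks$k, ks$ridge)
      fin <- bold_coef_at(envs[[i]], ks$k, sc$T0, sc$T1, ridge = ks$ridge)
    } else {
      e <- envs[[i]]
      sc <- x_scan(e, ks$k, ks$ridge)
      fin <- ssr_coef_at(e$t, e$x, e$xx, ks$k, sc$T0, sc$T1, T_ref,
                         ridge = ks$ridge)
    }
    two_state_params(a = fin$coef[1], b = fin$coef[2], c_amp = fin$coef[3],
                     k = ks$k, T0 = sc$T0, T1 = sc$T1, T_ref = T_ref)
  })
  names(fits) <- names(x_list)
  attr(fits, "ssr") <- ks$ssr
  fits
}

#' Relative capacity parameters derived from a fitted response
#'
#' The impulse-input model identifies only ratios: with
#' `H(t) = alpha * delta(t)`, the fitted amplitude is `a = alpha/m` and the
#' decay rate `k = p/m`, so the reportable quantities are the relative
#' processing capacity `p/alpha = k / a_ref`, the relative storage capacity
#' `m/alpha = 1 / a_ref`, and the time constant `T_c = m/p = 1/k` —
#' `a_ref` being the fitted amplitude of the normalization (reference)
#' condition.
#'
#' @param params a [two_state_params()] fit.
#' @param reference_amp fitted amplitude of the reference condition
#'   (default: the fit's own `a`).
#' @param hrf optional [hrf_params()]; when given, the time-to-peak of the
#'   predicted BOLD is located on a dense 0.1 s grid (earliest peak on
#'   ties).
#' @return list of class `derived_capacities`: `rel_processing`
#'   (`p/alpha`), `rel_storage` (`m/alpha`), `t_const` (s), `t_peak` (s or
#'   NA).
#' @export
derive_capacities <- function(params, reference_amp = params$a, hrf = NULL) {
  stopifnot(inherits(params, "two_state_params"))
  if (reference_amp <= 0)
    stop("'reference_amp' must be positive to normalize capacities",
         call. = FALSE)
  t_peak <- NA_real_
  if (!is.null(hrf)) {
    g <- seq(0, 32, by = 0.1)
    y <- convolve_bold(two_state_response(params, g), hrf_kernel(hrf, g))
    t_peak <- g[which.max(y$values)]  # which.max takes the earliest max
  }
  structure(list(rel_processing = params$k / reference_amp,
                 rel_storage = 1 / reference_amp,
                 t_const = 1 / params$k,
                 t_peak = t_peak),
            class = "derived_capacities")
}

#' @export
print.derived_capacities <- function(x, ...) {
  cat(sprintf(
    "<derived_capacities> p/alpha = %.4g /s, m/alpha = %.4g, T_c = %.4g s, T_y = %s s\n",
    x$rel_processing, x$rel_storage, x$t_const,
    if (is.na(x$t_peak)) "NA" else format(x$t_peak)))
  invisible(x)
}

#' Predict BOLD from a fitted response and score the fit
#'
#' Evaluates the fitted two-state response on a fine grid, convolves it
#' with the HRF, samples at the data TR and reports the mean squared error
#' against the observed BOLD.
#'
#' @param params a [two_state_params()] fit.
#' @param hrf the [hrf_params()] used for prediction.
#' @param y_obs observed sampled BOLD [time_series()] at the TR.
#' @param fine_dt fine grid step for the convolution (s).
#' @return list of class `fit_result`: `params`, `mse`, `y_pred`
#'   ([time_series()] at the TR), `hrf_used`.
#' @export
predict_and_score <- function(params, hrf, y_obs, fine_dt = 0.1) {
  stopifnot(inherits(params, "two_state_params"),
            inherits(hrf, "hrf_params"), inherits(y_obs, "ipc_ts"))
  tr <- y_obs$dt
  if (abs(tr / fine_dt - round(tr / fine_dt)) > 1e-8)
    stop("'fine_dt' must divide the data TR", call. = FALSE)
  t_end <- (length(y_obs$values) - 1L) * tr
  g <- seq(0, t_end + 32, by = fine_dt)
  y_fine <- convolve_bold(two_state_response(params, g),
                          hrf_kernel(hrf, seq(0, 32, by = fine_dt)))
  y_pred <- sample_and_noise(y_fine, tr)
  y_pred <- time_series(y_pred$values[seq_along(y_obs$values)], dt = tr,
                        t0 = y_obs$t0)
  structure(list(params = params,
                 mse = mean((y_obs$values - y_pred$values)^2),
                 y_pred = y_pred, hrf_used = hrf),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> mse = %.4g\n", x$mse))
  print(x$params)
  invisible(x)
}

#' Deconvolve, fit and score one trial-averaged BOLD response
#'
#' Convenience wrapper running the inversion chain for a single candidate
#' HRF: [deconvolve_ls()] -> [spline_upsample()] -> [fit_two_state()]
#' (with BOLD-domain refinement) -> [predict_and_score()].
#'
#' @param y trial-averaged sampled BOLD [time_series()] at the TR.
#' @param hrf candidate [hrf_params()].
#' @param cfg a [deconv_config()].
#' @param ... passed to [fit_two_state()].
#' @return A `fit_result` with extra fields `x_est` (TR knots) and
#'   `x_fine` (upsampled response).
#' @export
fit_bold_response <- function(y, hrf, cfg = deconv_config(), ...) {
  x_knots <- deconvolve_ls(y, hrf, cfg)
  x_fine <- spline_upsample(x_knots, fine_dt = cfg$fine_dt)
  params <- fit_two_state(x_fine, y_obs = y, hrf = hrf,
                          fine_dt = cfg$fine_dt, ...)
  fr <- predict_and_score(params, hrf, y, fine_dt = cfg$fine_dt)
  fr$x_est <- x_knots
  fr$x_fine <- x_fine
  fr
}

#' Select a hemodynamic response function by prediction error
#'
#' Runs the full inversion for every candidate HRF and keeps the candidate
#' with the smallest mean squared BOLD prediction error. With
#' `mode = "flexible"` each dataset selects its own HRF; with
#' `mode = "fixed"` the winner on the designated reference dataset is
#' applied to all datasets.
#'
#' @param y a sampled BOLD [time_series()] or a named list of them
#'   (datasets, e.g. group x condition IRFs).
#' @param mode `"flexible"` or `"fixed"`.
#' @param candidates data.frame of candidate HRF shapes with columns among
#'   `alpha1`, `alpha2`, `beta1`, `beta2`, `c_ratio` (peak-normalized
#'   scale).
#' @param cfg a [deconv_config()].
#' @param reference name or index of the reference dataset in fixed mode.
#' @param ... passed to [fit_two_state()].
#' @return For a single series, list(`hrf`, `fit`); for a list of datasets,
#'   a named list of such pairs.
#' @export
select_hrf <- function(y, mode = c("flexible", "fixed"), candidates,
                       cfg = deconv_config(), reference = 1L, ...) {
  mode <- match.arg(mode)
  if (!is.data.frame(candidates) || nrow(candidates) == 0L)
    stop("'candidates' must be a non-empty data.frame of HRF shapes",
         call. = FALSE)
  make_hrf <- function(row) {
    args <- as.list(row)
    args <- args[names(args) %in%
                   c("alpha1", "alpha2", "beta1", "beta2", "c_ratio")]
    do.call(hrf_params, args)
  }
  pick <- function(y1) {
    best <- NULL
    for (i in seq_len(nrow(candidates))) {
      h <- make_hrf(candidates[i, , drop = FALSE])
      fr <- fit_bold_response(y1, h, cfg, ...)
      if (is.null(best) || fr$mse < best$fit$mse)
        best <- list(hrf = h, fit = fr)
    }
    best
  }
  if (inherits(y, "ipc_ts")) return(pick(y))
  stopifnot(is.list(y), length(y) >= 1L)
  if (mode == "flexible") {
    out <- lapply(y, pick)
  } else {
    ref <- pick(y[[reference]])
    out <- lapply(y, function(y1)
      list(hrf = ref$hrf, fit = fit_bold_response(y1, ref$hrf, cfg, ...)))
  }
  out
}
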