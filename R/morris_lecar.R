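# Morris-Lecar neuron model: deterministic vector field, stochastic simulation,
# and extraction of the invariant sets (equilibria, limit cycles) that serve as
# bridge boundary marginals.
#
# State is (v, w): membrane potential v (mV) and potassium channel activation
# w in [0, 1].  The membrane equation is
#   C dv/dt = -gCa m_inf(v) (v - VCa) - gK w (v - VK) - gL (v - VL) + I,
# with noise (when present) entering the v-equation only, and
#   dw/dt = phi (w_inf(v) - w) / tau_w(v),
# where the gating curves are logistic in tanh form (see ml_gating).

#' Morris-Lecar parameter presets
#'
#' Returns the full parameter record for one of the two standard regimes:
#' `"class_I"` (Hopf regime, input current I = 92 uA/cm2, bistable between a
#' stable focus and a large stable limit cycle) or `"class_II"` (homoclinic
#' regime, I = 37 uA/cm2, with a stable node, a saddle, a weakly attracting
#' spiral and a large stable periodic orbit).
#'
#' @param regime `"class_I"` or `"class_II"`.
#' @return An object of class `ml_params`: a named list with maximal
#'   conductances `gCa`, `gK`, `gL` (mS/cm2), reversal potentials `VCa`, `VK`,
#'   `VL` (mV), input current `I` (uA/cm2), capacitance `C` (uF/cm2),
#'   timescale ratio `phi`, gating parameters `V1`..`V4` (mV) and
#'   `regime_label`.
#' @examples
#' p <- ml_params("class_I")
#' ml_gating(p$V1, p)$m_inf  # 0.5 by construction
#' @export
ml_params <- function(regime = c("class_I", "class_II")) {
  regime <- match.arg(regime)
  p <- if (regime == "class_I") {
    list(gCa = 4.4, gK = 8, gL = 2, VCa = 120, VK = -84, VL = -60,
         I = 92, C = 20, phi = 0.04, V1 = -1.2, V2 = 18, V3 = 2, V4 = 30,
         regime_label = "class_I")
  } else {
    list(gCa = 4, gK = 8, gL = 2, VCa = 120, VK = -84, VL = -60,
         I = 37, C = 20, phi = 0.23, V1 = -1.2, V2 = 18, V3 = 12, V4 = 17.4,
         regime_label = "class_II")
  }
  class(p) <- "ml_params"
  validate_ml_params(p)
  p
}

validate_ml_params <- function(p) {
  stopifnot(inherits(p, "ml_params"))
  num <- c("gCa", "gK", "gL", "VCa", "VK", "VL", "I", "C", "phi",
           "V1", "V2", "V3", "V4")
  for (f in num) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]))
      stop(sprintf("ml_params field '%s' must be a finite scalar", f))
  }
  if (p$gCa <= 0 || p$gK <= 0 || p$gL <= 0) stop("conductances must be > 0")
  if (p$C <= 0) stop("capacitance C must be > 0")
  if (p$phi <= 0) stop("phi must be > 0")
  if (p$V2 == 0 || p$V4 == 0) stop("V2 and V4 must be nonzero")
  invisible(p)
}

#' @export
print.ml_params <- function(x, ...) {
  cat(sprintf("Morris-Lecar parameters [%s], I = %g uA/cm2\n",
              x$regime_label, x$I))
  cat(sprintf("  gCa=%g gK=%g gL=%g  VCa=%g VK=%g VL=%g  C=%g phi=%g\n",
              x$gCa, x$gK, x$gL, x$VCa, x$VK, x$VL, x$C, x$phi))
  cat(sprintf("  V1=%g V2=%g V3=%g V4=%g\n", x$V1, x$V2, x$V3, x$V4))
  invisible(x)
}

#' Steady-state gating curves
#'
#' Computes the calcium activation steady state
#' `m_inf(v) = 0.5 (1 + tanh((v - V1)/V2))`, the potassium activation steady
#' state `w_inf(v) = 0.5 (1 + tanh((v - V3)/V4))` and the (dimensionless)
#' potassium time-constant factor `tau_w(v) = 1 / cosh((v - V3)/(2 V4))`.
#'
#' @param v Membrane potential(s), mV. Vectorized.
#' @param p An [ml_params] object.
#' @return A list with numeric components `m_inf`, `w_inf`, `tau_w` of the
#'   same length as `v`.
#' @export
ml_gating <- function(v, p) {
  validate_ml_params(p)
  if (!is.numeric(v) || !all(is.finite(v))) stop("'v' must be finite numeric")
  list(m_inf = 0.5 * (1 + tanh((v - p$V1) / p$V2)),
       w_inf = 0.5 * (1 + tanh((v - p$V3) / p$V4)),
       tau_w = 1 / cosh((v - p$V3) / (2 * p$V4)))
}

#' Deterministic Morris-Lecar vector field
#'
#' @param state Numeric vector `c(v, w)` or an n x 2 matrix of states
#'   (columns v, w).
#' @param p An [ml_params] object.
#' @return The time derivative `(dv/dt, dw/dt)` in the same shape as `state`.
#' @export
ml_drift <- function(state, p) {
  validate_ml_params(p)
  X <- if (is.null(dim(state)) && length(state) == 2L) matrix(state, 1L, 2L)
       else as_sample_matrix(state, "state")
  if (ncol(X) != 2L) stop("state must have two components (v, w)")
  v <- X[, 1L]; w <- X[, 2L]
  gt <- ml_gating(v, p)
  dv <- (-p$gCa * gt$m_inf * (v - p$VCa) - p$gK * w * (v - p$VK) -
           p$gL * (v - p$VL) + p$I) / p$C
  dw <- p$phi * (gt$w_inf - w) / gt$tau_w
  out <- cbind(dv, dw, deparse.level = 0)
  if (is.null(dim(state)) && length(state) == 2L) drop(out) else out
}

#' Euler-Maruyama simulation of the stochastic Morris-Lecar model
#'
#' Integrates the model on the uniform grid `t_k = k T / N` with noise of
#' intensity `sigma(t)` entering the `v`-equation only; `w` is clamped to
#' `[0, 1]` after every step.
#'
#' @param p An [ml_params] object.
#' @param init A state `c(v, w)` or an m x 2 matrix of initial states (paths
#'   draw their starting points from the rows, with replacement when
#'   `n_paths != m`).
#' @param sigma Noise intensity: a nonnegative scalar or a [noise_schedule]
#'   evaluated on physical time `[0, T]`.
#' @param T Terminal time (ms), > 0.
#' @param N Number of Euler steps, >= 1.
#' @param n_paths Number of sample paths.
#' @param seed Optional integer seed; the same seed reproduces the ensemble
#'   exactly.
#' @return A [trajectory_ensemble] with `states[n_paths, N + 1, 2]`.
#' @export
ml_simulate <- function(p, init, sigma = 0, T = 20, N = 200, n_paths = 1,
                        seed = NULL) {
  validate_ml_params(p)
  if (!is.numeric(T) || T <= 0) stop("T must be > 0")
  if (!is.numeric(N) || N < 1) stop("N must be >= 1")
  sig_fun <- as_sigma_function(sigma)
  X0 <- if (is.null(dim(init)) && length(init) == 2L) matrix(init, 1L, 2L)
        else as_sample_matrix(init, "init")
  if (ncol(X0) != 2L) stop("init must be states (v, w)")
  dt <- T / N
  times <- seq(0, T, length.out = N + 1L)
  with_seed(seed, {
    idx <- if (nrow(X0) == n_paths) seq_len(n_paths)
           else sample.int(nrow(X0), n_paths, replace = TRUE)
    X <- X0[idx, , drop = FALSE]
    states <- array(NA_real_, dim = c(n_paths, N + 1L, 2L))
    states[, 1L, ] <- X
    sqdt <- sqrt(dt)
    for (k in seq_len(N)) {
      d <- ml_drift(X, p)
      s <- sig_fun(times[k])
      X[, 1L] <- X[, 1L] + dt * d[, 1L] + s * sqdt * stats::rnorm(n_paths)
      X[, 2L] <- pmin(pmax(X[, 2L] + dt * d[, 2L], 0), 1)
      states[, k + 1L, ] <- X
    }
    trajectory_ensemble(states, times, direction = "forward", seed = seed)
  })
}

as_sigma_function <- function(sigma) {
  if (inherits(sigma, "noise_schedule")) return(function(t) sigma$sigma(t))
  if (is.function(sigma)) return(sigma)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  function(t) rep_len(sigma, length(t))
}

#' Locate equilibria of a planar vector field by multi-start Newton iteration
#'
#' Starts damped Newton iterations (finite-difference Jacobians) from a
#' regular `grid_n` x `grid_n` grid over the supplied box, merges duplicate
#' roots, and classifies each equilibrium from the Jacobian eigenvalues.
#'
#' @param f Vector field `function(X)` mapping an n x 2 state matrix to an
#'   n x 2 derivative matrix (e.g. `function(X) ml_drift(X, p)`).
#' @param lower,upper Numeric length-2 bounds of the search box.
#' @param grid_n Starts per axis (default 50).
#' @param tol Residual norm below which a point counts as a root.
#' @param merge_tol Length-2 tolerance for merging duplicate roots
#'   (default 0.5 in the first coordinate, 0.01 in the second).
#' @return A list of `invariant_set` objects of kind `"equilibrium"`, each
#'   with `points` (1 x 2 matrix), `stability` (complex eigenvalue pair) and
#'   a `stable` flag. Empty list when no root is found.
#' @export
find_equilibria <- function(f, lower = c(-80, 0), upper = c(60, 1),
                            grid_n = 50, tol = 1e-8,
                            merge_tol = c(0.5, 0.01)) {
  g1 <- seq(lower[1], upper[1], length.out = grid_n)
  g2 <- seq(lower[2], upper[2], length.out = grid_n)
  X <- as.matrix(expand.grid(g1, g2))
  colnames(X) <- NULL
  scale <- pmax(abs(upper - lower), 1)
  h <- 1e-6 * scale
  # vectorized damped Newton across all starts at once
  for (iter in 1:80) {
    Fx <- f(X)
    # finite-difference Jacobian entries, all starts in parallel
    J11 <- (f(cbind(X[, 1] + h[1], X[, 2]))[, 1] -
              f(cbind(X[, 1] - h[1], X[, 2]))[, 1]) / (2 * h[1])
    J21 <- (f(cbind(X[, 1] + h[1], X[, 2]))[, 2] -
              f(cbind(X[, 1] - h[1], X[, 2]))[, 2]) / (2 * h[1])
    J12 <- (f(cbind(X[, 1], X[, 2] + h[2]))[, 1] -
              f(cbind(X[, 1], X[, 2] - h[2]))[, 1]) / (2 * h[2])
    J22 <- (f(cbind(X[, 1], X[, 2] + h[2]))[, 2] -
              f(cbind(X[, 1], X[, 2] - h[2]))[, 2]) / (2 * h[2])
    det <- J11 * J22 - J12 * J21
    det[abs(det) < 1e-14] <- NA_real_
    d1 <- (J22 * Fx[, 1] - J12 * Fx[, 2]) / det
    d2 <- (J11 * Fx[, 2] - J21 * Fx[, 1]) / det
    step_cap <- 0.25 * scale  # damp huge steps from near-singular Jacobians
    d1 <- pmin(pmax(d1, -step_cap[1]), step_cap[1])
    d2 <- pmin(pmax(d2, -step_cap[2]), step_cap[2])
    ok <- is.finite(d1) & is.finite(d2)
    X[ok, 1] <- X[ok, 1] - d1[ok]
    X[ok, 2] <- X[ok, 2] - d2[ok]
    X[!ok, ] <- NA_real_
  }
  Fx <- f(ifelse(is.finite(X), X, 0))
  res <- sqrt(Fx[, 1]^2 + Fx[, 2]^2)
  keep <- which(is.finite(X[, 1]) & is.finite(X[, 2]) & res < tol &
                  X[, 1] > lower[1] - 10 * merge_tol[1] &
                  X[, 1] < upper[1] + 10 * merge_tol[1] &
                  X[, 2] > lower[2] - 10 * merge_tol[2] &
                  X[, 2] < upper[2] + 10 * merge_tol[2])
  roots <- list()
  for (i in keep) {
    x <- X[i, ]
    dup <- any(vapply(roots, function(r)
      abs(r[1] - x[1]) < merge_tol[1] && abs(r[2] - x[2]) < merge_tol[2],
      logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- x
  }
  lapply(roots, function(x) {
    J <- fd_jacobian_2d(f, x, h)
    ev <- eigen(J, only.values = TRUE)$values
    invariant_set("equilibrium", matrix(x, 1, 2), stability = ev,
                  stable = all(Re(ev) < 0))
  })
}

fd_jacobian_2d <- function(f, x, h) {
  f1p <- f(matrix(c(x[1] + h[1], x[2]), 1)); f1m <- f(matrix(c(x[1] - h[1], x[2]), 1))
  f2p <- f(matrix(c(x[1], x[2] + h[2]), 1)); f2m <- f(matrix(c(x[1], x[2] - h[2]), 1))
  cbind(as.numeric(f1p - f1m) / (2 * h[1]), as.numeric(f2p - f2m) / (2 * h[2]))
}

#' @rdname find_equilibria
#' @param p An [ml_params] object.
#' @param ... Passed on to [find_equilibria()].
#' @export
ml_find_equilibria <- function(p, ...) {
  validate_ml_params(p)
  find_equilibria(function(X) ml_drift(X, p), ...)
}

# Container for invariant-set samples.
invariant_set <- function(kind, points, period = NULL, stability = NULL,
                          stable = NA) {
  structure(list(kind = kind, points = points, period = period,
                 stability = stability, stable = stable),
            class = "invariant_set")
}

#' @export
print.invariant_set <- function(x, ...) {
  cat(sprintf("invariant set [%s], %d point(s)", x$kind, nrow(x$points)))
  if (!is.null(x$period)) cat(sprintf(", period %.3f ms", x$period))
  if (!is.na(x$stable)) cat(if (x$stable) ", stable" else ", unstable")
  cat("\n")
  invisible(x)
}

#' Extract a stable periodic orbit by long deterministic integration
#'
#' Integrates the deterministic model from `x0`, discards a transient, then
#' detects the period from successive upward crossings of the time-mean
#' membrane potential and returns one time-ordered cycle of orbit samples.
#'
#' @param p An [ml_params] object.
#' @param x0 Initial state in the oscillatory basin.
#' @param t_transient Transient time to discard (ms).
#' @param t_sample Sampling window after the transient (ms); must cover at
#'   least two oscillation periods.
#' @param dt Integration step (ms).
#' @return An `invariant_set` of kind `"limit_cycle"` whose `points` trace one
#'   period (first and last points close to within the closure tolerance) and
#'   whose `period` is the mean inter-crossing interval.
#' @export
ml_extract_limit_cycle <- function(p, x0 = c(0, 0), t_transient = 500,
                                   t_sample = 500, dt = 0.01) {
  validate_ml_params(p)
  n_tr <- round(t_transient / dt)
  n_sm <- round(t_sample / dt)
  x <- ml_integrate_det(p, as.numeric(x0), n_tr, dt, record = FALSE)
  tr <- ml_integrate_det(p, x, n_sm, dt, record = TRUE)
  vbar <- mean(tr[, 1])
  up <- which(tr[-nrow(tr), 1] < vbar & tr[-1L, 1] >= vbar)
  if (length(up) < 2L) stop("no oscillation detected")
  periods <- diff(up) * dt
  period <- mean(periods)
  if (stats::sd(tr[, 1]) < 1e-6) stop("no oscillation detected")
  cyc <- tr[up[1]:up[2], , drop = FALSE]
  closure <- sqrt(sum((cyc[1L, ] - cyc[nrow(cyc), ])^2))
  if (closure > 1) stop("orbit failed to close (closure distance ", closure, ")")
  invariant_set("limit_cycle", cyc, period = period, stable = TRUE)
}

# Tight scalar Euler loop for long deterministic runs (avoids per-step
# validation/dispatch overhead). Returns the endpoint, or the recorded
# (n_steps + 1) x 2 trajectory when record = TRUE.
ml_integrate_det <- function(p, x, n_steps, dt, record = FALSE) {
  gCa <- p$gCa; gK <- p$gK; gL <- p$gL; VCa <- p$VCa; VK <- p$VK; VL <- p$VL
  I <- p$I; C <- p$C; phi <- p$phi
  V1 <- p$V1; V2 <- p$V2; V3 <- p$V3; V4 <- p$V4
  v <- x[1]; w <- x[2]
  tr <- if (record) matrix(NA_real_, n_steps + 1L, 2L)
  if (record) tr[1L, ] <- c(v, w)
  for (k in seq_len(n_steps)) {
    minf <- 0.5 * (1 + tanh((v - V1) / V2))
    winf <- 0.5 * (1 + tanh((v - V3) / V4))
    dv <- (-gCa * minf * (v - VCa) - gK * w * (v - VK) - gL * (v - VL) + I) / C
    dw <- phi * (winf - w) * cosh((v - V3) / (2 * V4))
    v <- v + dt * dv
    w <- w + dt * dw
    if (w < 0) w <- 0 else if (w > 1) w <- 1
    if (record) tr[k + 1L, ] <- c(v, w)
  }
  if (record) tr else c(v, w)
}

#' Build boundary marginals for the node-to-cycle transition
#'
#' Constructs the empirical initial density `rho0` (Gaussian jitter around the
#' stable equilibrium) and target density `rho1` (uniform resampling along an
#' arc of the extracted stable periodic orbit, with the same jitter), as used
#' for bridging between the resting state and the oscillatory invariant set.
#'
#' @param p An [ml_params] object.
#' @param mode `"node_to_cycle"` (Class I limit cycle) or
#'   `"node_to_homoclinic"` (Class II large periodic orbit near the
#'   homoclinic regime). The mode must match the regime of `p`.
#' @param n Samples per marginal.
#' @param jitter_sd Isotropic Gaussian jitter (applied to both coordinates;
#'   mV in v, dimensionless in w).
#' @param arc_fraction Fraction (0, 1] of the cycle, by time along the orbit,
#'   that the target occupies.
#' @param seed Optional seed.
#' @param x0 Initial condition for cycle extraction (default chosen per mode).
#' @return List with `rho0` and `rho1`, both n x 2 matrices (columns v, w),
#'   plus the extracted `cycle`.
#' @export
ml_make_marginals <- function(p, mode = c("node_to_cycle", "node_to_homoclinic"),
                              n = 1000, jitter_sd = 0.5, arc_fraction = 0.25,
                              seed = NULL, x0 = NULL) {
  mode <- match.arg(mode)
  validate_ml_params(p)
  if (arc_fraction <= 0 || arc_fraction > 1) stop("arc_fraction must be in (0, 1]")
  eqs <- ml_find_equilibria(p, grid_n = 25)
  stable <- Filter(function(e) isTRUE(e$stable), eqs)
  if (length(stable) == 0L) stop("no stable equilibrium found")
  # the resting state: the most hyperpolarized stable equilibrium
  vs <- vapply(stable, function(e) e$points[1, 1], numeric(1))
  node <- stable[[which.min(vs)]]$points[1, ]
  if (is.null(x0)) x0 <- if (mode == "node_to_cycle") c(0, 0) else c(-20, 0.02)
  cyc <- ml_extract_limit_cycle(p, x0 = x0,
                                t_transient = if (mode == "node_to_cycle") 500 else 2000,
                                t_sample = if (mode == "node_to_cycle") 500 else 2000)
  m <- nrow(cyc$points)
  with_seed(seed, {
    rho0 <- cbind(node[1] + stats::rnorm(n, 0, jitter_sd),
                  node[2] + stats::rnorm(n, 0, jitter_sd))
    arc_len <- max(1L, round(arc_fraction * m))
    arc_idx <- seq_len(arc_len)
    pick <- arc_idx[sample.int(arc_len, n, replace = TRUE)]
    rho1 <- cyc$points[pick, , drop = FALSE] +
      cbind(stats::rnorm(n, 0, jitter_sd), stats::rnorm(n, 0, jitter_sd))
    colnames(rho0) <- colnames(rho1) <- c("v", "w")
    list(rho0 = rho0, rho1 = rho1, cycle = cyc)
  })
}
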