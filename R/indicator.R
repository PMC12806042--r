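# Action-functional early-warning indicator on the flow of bridge marginals:
# the time-averaged kinetic energy of the transporting velocity field,
#   I(t) = (1/t) int_0^t E ||v(s, X_s)||^2 ds,
# estimated by a left-point Riemann sum over the model grid and a Monte-Carlo
# average over a forward trajectory ensemble.  A tipping point announces
# itself as a qualitative jump in the increments of I.

#' Velocity field of a bridge model
#'
#' The velocity transporting the bridge marginals. `mode = "full"` (default)
#' is `v = f + sigma_t^2 grad ln phi_t`, the drift of the forward SDE in
#' physical time; `mode = "control"` is the control-only part
#' `u = sigma_t^2 grad ln phi_t`.
#'
#' @param m A [bridge_model].
#' @param mode `"full"` or `"control"`.
#' @return `function(s, X)` of internal time `s` in `[0, 1]` and an n x d
#'   state matrix, returning the n x d physical velocity.
#' @export
velocity_field <- function(m, mode = c("full", "control")) {
  mode <- match.arg(mode)
  g <- model_grid(m)
  function(s, X) {
    sig <- m$schedule$sigma(s * m$T) * sqrt(m$T)
    v_int <- sig * sf_eval(m$z_fwd, s, X)
    if (mode == "full") v_int <- v_int + model_drift(m, s, X)
    v_int / m$T  # internal drift -> physical velocity (ds = dt / T)
  }
}

#' Action-functional indicator series
#'
#' Computes the instantaneous action `a_k = E ||v(t_k, X_{t_k})||^2`, the
#' running indicator `I(t_k) = (1/t_k) sum_{j<k} a_j dt` (left-point rule;
#' `I` is reported from the first positive time), and its absolute increments.
#'
#' @param m A [bridge_model].
#' @param ens A forward [trajectory_ensemble] sampled from `m`.
#' @param mode Velocity mode, see [velocity_field()].
#' @return An object of class `indicator_series`: a data frame with columns
#'   `step`, `t`, `I`, `dI`, `a_inst` (dI is `|I_{k+1} - I_k|`, NA in the
#'   last row), with attribute `total_action` = `int_0^T E||v||^2 dt`.
#' @export
action_indicator <- function(m, ens, mode = "full") {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  if (dim(ens$states)[2] != m$N + 1L)
    stop("ensemble grid does not match model grid")
  vf <- velocity_field(m, mode)
  g <- model_grid(m)
  dt_phys <- m$T / m$N
  a <- numeric(m$N)  # a_k at left points t_0 .. t_{N-1}
  for (k in seq_len(m$N)) {
    X <- slice_states(ens, k)
    V <- vf(g$s[k], X)
    a[k] <- mean(rowSums(V^2))
  }
  t_k <- g$t_phys[-1]                      # t_1 .. t_N (positive times)
  I <- cumsum(a) * dt_phys / t_k
  s <- data.frame(step = seq_len(m$N), t = t_k, I = I,
                  dI = c(abs(diff(I)), NA_real_), a_inst = a)
  class(s) <- c("indicator_series", "data.frame")
  attr(s, "total_action") <- sum(a) * dt_phys
  s
}

#' Detect a tipping step in an indicator series
#'
#' With a numeric threshold `C`, returns the smallest step whose increment
#' `|I_{k+1} - I_k|` reaches `C` (or `NULL` if none does). With `C = "auto"`,
#' returns the argmax increment together with its magnitude and a robust
#' z-score against the median/MAD of all increments (`NULL` when the series
#' is constant, i.e. zero MAD).
#'
#' @param s An `indicator_series` (or data frame with columns `step`, `I`).
#' @param C Numeric threshold, or `"auto"`.
#' @return `NULL`, or `list(step =, dI =, zscore =)` (`zscore` only in auto
#'   mode).
#' @export
detect_tipping <- function(s, C = "auto") {
  stopifnot(is.data.frame(s), all(c("step", "I") %in% names(s)))
  if (nrow(s) < 3L) stop("need at least 3 indicator values")
  dI <- abs(diff(s$I))
  steps <- s$step[-nrow(s)]
  if (is.numeric(C)) {
    hit <- which(dI >= C)
    if (length(hit) == 0L) return(NULL)
    k <- hit[1L]
    return(list(step = steps[k], dI = dI[k]))
  }
  if (!identical(C, "auto")) stop("C must be numeric or \"auto\"")
  med <- stats::median(dI)
  mad <- stats::mad(dI)
  if (mad == 0) return(NULL)
  k <- which.max(dI)
  list(step = steps[k], dI = dI[k], zscore = (dI[k] - med) / mad)
}
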