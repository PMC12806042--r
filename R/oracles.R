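# Closed-form Gaussian references: Bures-Wasserstein distance and the 1-D
# Gaussian Schrodinger-bridge (entropic interpolation) marginals and score.
#
# Derivation used below (1-D, zero reference drift, constant noise g on the
# unit time interval): the static bridge coupling is the entropy-regularized
# optimal plan between N(mu0, s0^2) and N(mu1, s1^2); within the Gaussian
# family its cross-covariance c maximizes  c/g^2 + (1/2) ln(s0^2 s1^2 - c^2),
# giving  c = ( -g^2 + sqrt(g^4 + 4 s0^2 s1^2) ) / 2.  Conditionally on the
# endpoints the bridge is Brownian, so the time-t marginal is Gaussian with
#   mean(t) = (1 - t) mu0 + t mu1
#   var(t)  = (1-t)^2 s0^2 + t^2 s1^2 + 2 t (1-t) c + g^2 t (1-t).
# As g -> 0, c -> s0 s1 and var(t) -> ((1-t) s0 + t s1)^2, the displacement
# (McCann) interpolation.

#' Gaussian specification
#'
#' @param mean Mean vector.
#' @param cov Covariance matrix (or scalar variance in 1-D).
#' @return Object of class `gaussian_spec`.
#' @export
gaussian_spec <- function(mean, cov) {
  mean <- as.numeric(mean)
  if (is.null(dim(cov))) cov <- diag(as.numeric(cov), length(mean))
  cov <- as.matrix(cov)
  if (!isSymmetric(unname(cov), tol = 1e-10))
    stop("covariance must be symmetric")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("covariance must be positive definite")
  structure(list(mean = mean, cov = cov), class = "gaussian_spec")
}

#' Squared 2-Wasserstein (Bures) distance between Gaussians
#'
#' `||mu_a - mu_b||^2 + tr(Sa + Sb - 2 (Sb^{1/2} Sa Sb^{1/2})^{1/2})`.
#'
#' @param a,b [gaussian_spec] objects of equal dimension.
#' @return Scalar squared distance.
#' @export
bures_w2 <- function(a, b) {
  stopifnot(inherits(a, "gaussian_spec"), inherits(b, "gaussian_spec"),
            length(a$mean) == length(b$mean))
  msqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  }
  Rb <- msqrt(b$cov)
  cross <- msqrt(Rb %*% a$cov %*% Rb)
  sum((a$mean - b$mean)^2) +
    sum(diag(a$cov)) + sum(diag(b$cov)) - 2 * sum(diag(cross))
}

#' Time marginals of the 1-D Gaussian Schrodinger bridge
#'
#' Closed-form mean and variance of the entropic interpolation between two
#' 1-D Gaussians under a Brownian reference of intensity `g` on the unit time
#' interval (see the derivation at the top of the source file). Endpoints
#' reproduce the marginals exactly.
#'
#' @param a,b 1-D [gaussian_spec] objects.
#' @param g Noise intensity, > 0.
#' @param t_grid Times in `[0, 1]`.
#' @return Data frame with columns `t`, `mean`, `var`.
#' @export
gaussian_sb_closed_form <- function(a, b, g, t_grid) {
  stopifnot(inherits(a, "gaussian_spec"), inherits(b, "gaussian_spec"),
            length(a$mean) == 1L, length(b$mean) == 1L)
  if (g <= 0) stop("g must be > 0 (use bures_w2 / displacement interpolation for the limit)")
  s0sq <- a$cov[1, 1]; s1sq <- b$cov[1, 1]
  cc <- (-g^2 + sqrt(g^4 + 4 * s0sq * s1sq)) / 2
  t <- as.numeric(t_grid)
  data.frame(
    t = t,
    mean = (1 - t) * a$mean + t * b$mean,
    var = (1 - t)^2 * s0sq + t^2 * s1sq + 2 * t * (1 - t) * cc +
      g^2 * t * (1 - t))
}

#' Closed-form score field of the 1-D Gaussian bridge
#'
#' Returns the exact forward (or backward) score field of the 1-D Gaussian
#' bridge as a `score_field` usable in [propagate_forward()] /
#' [propagate_backward()]. Because the bridge marginals `N(mu_t, s_t^2)` are
#' generated by a linear SDE, `g^2 d(ln phi_t)/dx = a_t x + b_t` with
#' `a_t = (d s_t^2/dt - g^2) / (2 s_t^2)` and `b_t = d mu_t/dt - a_t mu_t`;
#' the score `Z = (a_t x + b_t) / g`. The backward field is the forward field
#' of the time-reversed bridge (marginals swapped).
#'
#' @inheritParams gaussian_sb_closed_form
#' @param direction `"forward"` (score of phi) or `"backward"` (score of
#'   phi-hat, to be used with [propagate_backward()]).
#' @return A `score_field`.
#' @export
gaussian_bridge_score <- function(a, b, g, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (direction == "backward") { tmp <- a; a <- b; b <- tmp }
  s0sq <- a$cov[1, 1]; s1sq <- b$cov[1, 1]
  mu0 <- a$mean; mu1 <- b$mean
  cc <- (-g^2 + sqrt(g^4 + 4 * s0sq * s1sq)) / 2
  varfun <- function(t) (1 - t)^2 * s0sq + t^2 * s1sq +
    2 * t * (1 - t) * cc + g^2 * t * (1 - t)
  dvarfun <- function(t) -2 * (1 - t) * s0sq + 2 * t * s1sq +
    2 * (1 - 2 * t) * cc + g^2 * (1 - 2 * t)
  fn <- function(t, X) {
    # for the backward field, internal time runs against physical time
    tt <- if (direction == "backward") 1 - t else t
    at <- (dvarfun(tt) - g^2) / (2 * varfun(tt))
    bt <- (mu1 - mu0) - at * ((1 - tt) * mu0 + tt * mu1)
    matrix((at * X[, 1] + bt) / g, ncol = 1)
  }
  score_function(fn, d = 1L)
}
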