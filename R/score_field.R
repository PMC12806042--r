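# Trainable score fields Z(t, x; theta) approximating sigma_t grad ln phi_t
# (forward role) or sigma_t grad ln phi_hat_t (backward role).
#
# The workhorse is a single-hidden-layer tanh perceptron on the input
# u = (x, 2t - 1) with analytic evaluation, analytic state-Jacobian (hence an
# exact divergence), and hand-derived parameter gradients for the stage
# objectives used in likelihood training (see train.R).  One hidden layer
# keeps every quantity -- including the parameter gradient of the divergence
# term, which involves second derivatives of the activation -- in closed form,
# which is what makes CPU-only training practical here; for the 1-D and 2-D
# problems this package targets the capacity is ample.

#' Multilayer-perceptron score field
#'
#' @param d State dimension.
#' @param hidden Hidden-layer width.
#' @param init_scale Standard deviation of the Gaussian weight initialization;
#'   small values start the field near zero, i.e. near the reference process.
#' @param gain Fixed output gain: the field evaluates to `gain` times the
#'   network output. Training sets `gain = 1/sigma_bar` (the mean effective
#'   noise), so the network itself works in drift units `sigma * Z` and its
#'   weights stay O(1) no matter how small the noise is -- low-noise bridges
#'   need scores of magnitude 1/sigma, which a unit-gain network would have
#'   to reach through many small optimizer steps.
#' @param seed Optional seed for the initialization.
#' @return An object of class `c("score_mlp", "score_field")` holding the
#'   hidden-layer matrices `W1` (H x (d+1)), `b1`, the output layer `W2`
#'   (d x H), `b2`, and a linear skip connection `W3` (d x (d+1), initialized
#'   at zero) that lets the field represent large affine components without
#'   saturating the tanh units.
#' @export
score_mlp <- function(d, hidden = 48, init_scale = 0.05, gain = 1, seed = NULL) {
  with_seed(seed, {
    p_in <- d + 1L
    structure(list(
      d = d, hidden = hidden, gain = gain,
      W1 = matrix(stats::rnorm(hidden * p_in, 0, init_scale / sqrt(p_in)), hidden, p_in),
      b1 = stats::rnorm(hidden, 0, init_scale),
      W2 = matrix(stats::rnorm(d * hidden, 0, init_scale / sqrt(hidden)), d, hidden),
      b2 = rep(0, d),
      W3 = matrix(0, d, p_in)),
      class = c("score_mlp", "score_field"))
  })
}

#' Zero score field
#' @param d State dimension.
#' @export
score_zero <- function(d) {
  structure(list(d = d), class = c("score_zero", "score_field"))
}

#' Constant score field
#' @param value Numeric vector: the constant output.
#' @export
score_constant <- function(value) {
  structure(list(d = length(value), value = as.numeric(value)),
            class = c("score_constant", "score_field"))
}

#' Score field from a plain function
#' @param fn `function(t, X)` returning an n x d matrix; `t` is the internal
#'   time in `[0, 1]` (scalar or length n).
#' @param d State dimension.
#' @export
score_function <- function(fn, d) {
  structure(list(fn = fn, d = d), class = c("score_function", "score_field"))
}

#' Evaluate a score field
#'
#' @param field A `score_field` object.
#' @param t Internal time in `[0, 1]`, scalar or one value per row of `X`.
#' @param X n x d state matrix.
#' @return n x d matrix of field values.
#' @export
sf_eval <- function(field, t, X) UseMethod("sf_eval")

#' @export
sf_eval.score_zero <- function(field, t, X) matrix(0, nrow(X), field$d)

#' @export
sf_eval.score_constant <- function(field, t, X)
  matrix(field$value, nrow(X), field$d, byrow = TRUE)

#' @export
sf_eval.score_function <- function(field, t, X) field$fn(t, X)

#' @export
sf_eval.score_mlp <- function(field, t, X) {
  fwd <- mlp_forward(field, t, X)
  fwd$Z
}

# Shared forward pass: U is the feature matrix (x, 2t - 1), A = tanh(U W1' + b1).
mlp_forward <- function(field, t, X) {
  n <- nrow(X)
  tt <- rep_len(t, n)
  U <- cbind(X, 2 * tt - 1)
  H <- U %*% t(field$W1)
  H <- sweep(H, 2L, field$b1, "+")
  A <- tanh(H)
  Z <- A %*% t(field$W2) + U %*% t(field$W3)
  Z <- sweep(Z, 2L, field$b2, "+")
  list(U = U, A = A, Z = Z * (field$gain %||% 1))
}

#' Divergence of a vector field with respect to the state
#'
#' For MLP score fields the divergence
#' `sum_i dZ_i/dx_i = sum_m (1 - A_m^2) s_m`, with
#' `s_m = sum_i W2[i, m] W1[m, i]`, is evaluated analytically. For the other
#' field types it is exact by construction (zero/constant) or computed by
#' central finite differences (exact for fields quadratic in the state).
#'
#' @param field A `score_field`, or a plain `function(t, X)`.
#' @param t Internal time (scalar or per-row).
#' @param X n x d matrix of evaluation points.
#' @param h Finite-difference step for generic fields.
#' @return Numeric vector of length n.
#' @export
field_divergence <- function(field, t, X, h = 1e-5) {
  X <- as_sample_matrix(X, "X")
  if (inherits(field, "score_mlp")) {
    fwd <- mlp_forward(field, t, X)
    d <- field$d
    s_vec <- colSums(t(field$W1[, seq_len(d), drop = FALSE]) * field$W2)
    skip_tr <- sum(diag(field$W3[, seq_len(d), drop = FALSE]))
    return((field$gain %||% 1) *
             (as.numeric((1 - fwd$A^2) %*% s_vec) + skip_tr))
  }
  if (inherits(field, "score_zero") || inherits(field, "score_constant"))
    return(rep(0, nrow(X)))
  fn <- if (inherits(field, "score_function")) field$fn
        else if (is.function(field)) field
        else stop("unsupported field type")
  out <- rep(0, nrow(X))
  for (i in seq_len(ncol(X))) {
    Xp <- X; Xp[, i] <- Xp[, i] + h
    Xm <- X; Xm[, i] <- Xm[, i] - h
    out <- out + (fn(t, Xp)[, i] - fn(t, Xm)[, i]) / (2 * h)
  }
  out
}

# ---- gradient machinery (internal) ------------------------------------------
#
# Stage objective per evaluation row (weight w_r, divergence weight omega_r):
#   w_r * ( 1/2 ||Z_r||^2 + <C_r, Z_r> ) + omega_r * div_x Z_r
# Gradients with respect to (W1, b1, W2, b2), summed over rows:
#   residual R = w * (Z + C)
#   dW2 = R' A + [div]  q_m W1x[m, i]        with q_m = sum_r omega_r (1 - A_rm^2)
#   db2 = colSums(R)
#   dH  = (R W2) * (1 - A^2) + [div] outer(omega, s) * (-2 A (1 - A^2))
#   dW1 = dH' U  + [div, x-columns only] q_m W2[i, m]
#   db1 = colSums(dH)
mlp_objective_grad <- function(field, U, A, Z, C, w, omega) {
  d <- field$d
  gain <- field$gain %||% 1
  # Z already includes the gain; chain rule scales all parameter gradients
  # (and the divergence weights) by gain.
  R <- (Z + C) * w * gain
  omega <- omega * gain
  gW2 <- t(R) %*% A
  gb2 <- colSums(R)
  gW3 <- t(R) %*% U
  dH <- (R %*% field$W2) * (1 - A^2)
  W1x <- field$W1[, seq_len(d), drop = FALSE]
  s_vec <- colSums(t(W1x) * field$W2)          # s_m = sum_i W2[i,m] W1[m,i]
  if (any(omega != 0)) {
    Ap <- 1 - A^2
    q <- as.numeric(t(Ap) %*% omega)           # q_m = sum_r omega_r (1 - A_rm^2)
    gW2 <- gW2 + t(W1x * q)
    dH <- dH + (omega %*% t(s_vec)) * (-2 * A * Ap)
    gW1 <- t(dH) %*% U
    gW1[, seq_len(d)] <- gW1[, seq_len(d)] + q * t(field$W2)
  } else {
    gW1 <- t(dH) %*% U
  }
  gb1 <- colSums(dH)
  if (any(omega != 0)) {
    # divergence of the skip path: sum of the diagonal x-block of W3
    diag_idx <- cbind(seq_len(d), seq_len(d))
    gW3[diag_idx] <- gW3[diag_idx] + sum(omega)
  }
  # objective value, for monitoring (omega here is already gain-scaled, and
  # the network-output divergence times gain is the field divergence)
  skip_tr <- sum(diag(field$W3[, seq_len(d), drop = FALSE]))
  val <- sum(w * (0.5 * rowSums(Z^2) + rowSums(C * Z))) +
    sum(omega * (as.numeric((1 - A^2) %*% s_vec) + skip_tr))
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, value = val)
}

# Adam optimizer state and update (internal).
adam_init <- function(field) {
  zeros <- lapply(field[c("W1", "b1", "W2", "b2", "W3")], function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(field, grad, state, lr = 5e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in c("W1", "b1", "W2", "b2", "W3")) {
    g <- grad[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    field[[nm]] <- field[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(field = field, state = state)
}
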