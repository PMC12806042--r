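# Semi-discrete optimal transport via the discrete Brenier potential:
# the convex potential max_i <x, y_i> + h_i induces a cell decomposition of
# the source; the height vector h is tuned so each cell carries its target
# atom's prescribed mass, giving a measure-preserving map onto the atoms.
# Used to split a connected source against a non-convex (multi-component)
# target before bridging each matched pair.

#' Target atom set
#'
#' @param Y m x d matrix of atom locations.
#' @param nu Positive weights, normalized to sum to 1.
#' @return Object of class `target_atoms`.
#' @export
target_atoms <- function(Y, nu = NULL) {
  Y <- as_sample_matrix(Y, "Y")
  m <- nrow(Y)
  nu <- nu %||% rep(1 / m, m)
  if (length(nu) != m || any(nu <= 0)) stop("weights must be positive, one per atom")
  nu <- nu / sum(nu)
  structure(list(Y = Y, nu = nu), class = "target_atoms")
}

#' Assign source points to Brenier cells
#'
#' Cell `W_i` is the region where the support plane `<x, y_i> + h_i` attains
#' the maximum; ties break to the lowest atom index.
#'
#' @param x A point, or an n x d matrix of points.
#' @param atoms A [target_atoms] object.
#' @param h Height vector (one value per atom; default 0).
#' @return Integer vector of atom indices.
#' @export
cell_assign <- function(x, atoms, h = rep(0, nrow(atoms$Y))) {
  X <- if (is.null(dim(x)) && length(x) == ncol(atoms$Y)) matrix(x, 1L)
       else as_sample_matrix(x, "x")
  S <- X %*% t(atoms$Y)
  S <- sweep(S, 2L, h, "+")
  max.col(S, ties.method = "first")
}

#' Monte-Carlo cell masses
#'
#' Fraction of source samples falling in each Brenier cell.
#'
#' @param source_samples n x d matrix of source samples.
#' @param atoms A [target_atoms] object.
#' @param h Height vector.
#' @return Numeric vector of masses summing to 1.
#' @export
cell_masses <- function(source_samples, atoms, h = rep(0, nrow(atoms$Y))) {
  X <- as_sample_matrix(source_samples, "source_samples")
  idx <- cell_assign(X, atoms, h)
  tabulate(idx, nbins = nrow(atoms$Y)) / nrow(X)
}

#' Transport energy and its gradient in the heights
#'
#' `E(h) = int_0^h sum_i omega_i(eta) d eta_i - sum_i h_i nu_i`, evaluated by
#' midpoint quadrature along the straight path `0 -> h` (the integrand is
#' piecewise constant in the heights, so only re-assignments matter); the
#' gradient is exactly `omega(h) - nu`.
#'
#' @inheritParams cell_masses
#' @param n_quad Quadrature points along the path.
#' @return `list(value =, gradient =)`.
#' @export
ot_energy_grad <- function(source_samples, atoms, h, n_quad = 64) {
  X <- as_sample_matrix(source_samples, "source_samples")
  taus <- (seq_len(n_quad) - 0.5) / n_quad
  val <- 0
  for (tau in taus) {
    om <- cell_masses(X, atoms, tau * h)
    val <- val + sum(om * h) / n_quad
  }
  val <- val - sum(h * atoms$nu)
  list(value = val, gradient = cell_masses(X, atoms, h) - atoms$nu)
}

#' Solve for the height vector of the semi-discrete transport map
#'
#' Gradient descent on `E(h)` (the unique minimizer up to an additive
#' constant) with step halving on residual non-decrease, until
#' `max_i |omega_i(h) - nu_i| < tol`. The gauge is fixed by `h_m = 0`.
#'
#' @inheritParams cell_masses
#' @param config `list(tol =, max_iters =, step =)`.
#' @return Numeric height vector (class `numeric`), gauge-fixed.
#' @export
solve_heights <- function(source_samples, atoms,
                          config = list(tol = 0.01, max_iters = 5000, step = NULL)) {
  X <- as_sample_matrix(source_samples, "source_samples")
  m <- nrow(atoms$Y)
  tol <- config$tol %||% 0.01
  max_iters <- config$max_iters %||% 5000
  # scale: a height offset of order (spread of <x, y_i>) moves whole cells
  spread <- stats::sd(as.numeric(X %*% t(atoms$Y)))
  step <- config$step %||% max(spread, 1e-8)
  h <- rep(0, m)
  if (m == 1L) return(h)
  best_res <- Inf
  for (it in seq_len(max_iters)) {
    grad <- cell_masses(X, atoms, h) - atoms$nu
    res <- max(abs(grad))
    if (res < tol) {
      h <- h - h[m]
      return(h)
    }
    if (res >= best_res) step <- step * 0.8 else best_res <- res
    if (step < 1e-12) break
    h <- h - step * grad
    h <- h - h[m]
  }
  stop(sprintf("solve_heights did not converge: residual %.4g after %d iterations",
               max(abs(cell_masses(X, atoms, h) - atoms$nu)), max_iters))
}

#' Split a source/target pair along target clusters
#'
#' Clusters the target samples into `n_clusters` components, treats the
#' cluster centroids as weighted atoms (weights = cluster sample fractions),
#' solves the semi-discrete transport from the source, and partitions the
#' source samples by cell so that each source part carries exactly its target
#' cluster's mass. Returns matched (source part, target cluster) pairs.
#'
#' @param rho0_samples,rho1_samples Source and target sample matrices.
#' @param n_clusters Number of target components.
#' @param config List: `method` (`"kmeans"`, the default, or `"single"` for
#'   single-linkage connected components), `seed` for k-means restarts, plus
#'   [solve_heights()] settings.
#' @return List with `pairs` (list of `list(rho0, rho1, weight, target_centroid)`),
#'   `assignment0`, `assignment1` (cluster index per sample), `atoms`, `h`.
#' @export
split_by_target_clusters <- function(rho0_samples, rho1_samples, n_clusters,
                                     config = list()) {
  X0 <- as_sample_matrix(rho0_samples, "rho0_samples")
  X1 <- as_sample_matrix(rho1_samples, "rho1_samples")
  stopifnot(n_clusters >= 1)
  method <- config$method %||% "kmeans"
  if (n_clusters == 1L) {
    cl <- rep(1L, nrow(X1))
  } else if (method == "kmeans") {
    cl <- with_seed(config$seed %||% 1L,
      stats::kmeans(X1, centers = n_clusters, nstart = 10)$cluster)
  } else if (method == "single") {
    cl <- stats::cutree(stats::hclust(stats::dist(X1), method = "single"),
                        k = n_clusters)
  } else stop("unknown clustering method")
  # stable cluster labelling: order by first coordinate of the centroid
  cent <- t(vapply(seq_len(n_clusters),
                   function(k) colMeans(X1[cl == k, , drop = FALSE]),
                   numeric(ncol(X1))))
  ord <- order(cent[, 1])
  relabel <- match(seq_len(n_clusters), ord)
  cl <- relabel[cl]
  cent <- cent[ord, , drop = FALSE]
  wts <- tabulate(cl, n_clusters) / length(cl)
  if (any(wts == 0)) stop("cluster weight = 0")
  atoms <- target_atoms(cent, wts)
  h <- solve_heights(X0, atoms, config)
  a0 <- cell_assign(X0, atoms, h)
  pairs <- lapply(seq_len(n_clusters), function(k)
    list(rho0 = X0[a0 == k, , drop = FALSE],
         rho1 = X1[cl == k, , drop = FALSE],
         weight = wts[k], target_centroid = cent[k, ]))
  list(pairs = pairs, assignment0 = a0, assignment1 = cl, atoms = atoms, h = h)
}

#' Quadratic cluster terminal loss
#'
#' Mean squared distance between propagated terminal states and their
#' source-cell target atoms: the terminal attachment that replaces the
#' terminal log-likelihood when the target is an empirical atom set. Entered
#' into the minimized loss with a positive sign (maximizing the terminal
#' likelihood of a cell target corresponds to minimizing the squared
#' distance to it).
#'
#' @param X1_batch n x d matrix of propagated terminal states.
#' @param assigned_targets n x d matrix: the target atom of each path's
#'   source cell.
#' @return Scalar mean squared distance.
#' @export
cluster_terminal_loss <- function(X1_batch, assigned_targets) {
  A <- as_sample_matrix(X1_batch, "X1_batch")
  B <- as_sample_matrix(assigned_targets, "assigned_targets")
  if (!all(dim(A) == dim(B))) stop("terminal states and targets differ in shape")
  mean(rowSums((A - B)^2))
}
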