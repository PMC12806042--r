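# Gaussian kernel density estimation on rectangular grids, and the
# forward/backward marginal-consistency diagnostic built on it.

#' Gaussian kernel density estimate on a rectangular grid
#'
#' Product-Gaussian KDE in one or two dimensions, evaluated on a regular grid.
#' When `grid_spec` is omitted the grid covers the samples plus three
#' bandwidths per side, so the trapezoid-rule integral of the estimate is
#' 1 to within a tolerance of about 1e-2.
#'
#' @param samples n x d matrix (d = 1 or 2) or numeric vector.
#' @param grid_spec `NULL`, or `list(lower =, upper =, n =)` with length-d
#'   bounds and grid sizes (scalar `n` recycled).
#' @param bandwidth Kernel standard deviation per dimension (scalar recycled);
#'   `NULL` uses Silverman's rule per coordinate.
#' @return An object of class `kde_grid`: `x` (list of axis vectors), `z`
#'   (vector for d = 1, matrix for d = 2), `bandwidth`, `dx`.
#' @export
kde_density <- function(samples, grid_spec = NULL, bandwidth = NULL) {
  X <- as_sample_matrix(samples, "samples")
  if (nrow(X) < 2L) stop("need at least 2 samples")
  d <- ncol(X)
  if (d > 2L) stop("kde_density supports 1-D and 2-D samples")
  if (is.null(bandwidth)) {
    bandwidth <- vapply(seq_len(d), function(j) silverman_bw(X[, j]), numeric(1))
  }
  bandwidth <- rep_len(bandwidth, d)
  if (any(bandwidth <= 0))
    stop("bandwidth must be positive (degenerate samples need an explicit bandwidth)")
  if (is.null(grid_spec)) {
    lower <- apply(X, 2, min) - 3 * bandwidth
    upper <- apply(X, 2, max) + 3 * bandwidth
    n <- rep_len(128L, d)
  } else {
    lower <- grid_spec$lower; upper <- grid_spec$upper
    n <- rep_len(grid_spec$n %||% 128L, d)
  }
  axes <- lapply(seq_len(d), function(j) seq(lower[j], upper[j], length.out = n[j]))
  # per-axis kernel matrices: K_j[grid, sample] = dnorm(g - x)
  K <- lapply(seq_len(d), function(j)
    outer(axes[[j]], X[, j], function(g, x) stats::dnorm(g, x, bandwidth[j])))
  z <- if (d == 1L) rowMeans(K[[1]])
       else (K[[1]] %*% t(K[[2]])) / nrow(X)
  structure(list(x = axes, z = z, bandwidth = bandwidth,
                 dx = vapply(axes, function(a) a[2] - a[1], numeric(1))),
            class = "kde_grid")
}

silverman_bw <- function(x) {
  n <- length(x)
  s <- min(stats::sd(x), stats::IQR(x) / 1.349)
  if (!is.finite(s) || s == 0) s <- stats::sd(x)
  0.9 * s * n^(-1 / 5)
}

#' Trapezoid-rule integral of a [kde_density()] grid
#' @param k A `kde_grid` object.
#' @return Scalar integral estimate.
#' @export
kde_integral <- function(k) {
  tw <- function(n) { w <- rep(1, n); w[c(1, n)] <- 0.5; w }
  if (is.matrix(k$z)) {
    w1 <- tw(nrow(k$z)) * k$dx[1]; w2 <- tw(ncol(k$z)) * k$dx[2]
    as.numeric(t(w1) %*% k$z %*% w2)
  } else sum(tw(length(k$z)) * k$z) * k$dx[1]
}

#' Forward/backward marginal consistency
#'
#' L1 distance between kernel density estimates of the forward and backward
#' ensembles' time marginals on a shared grid, per requested time. Agreement
#' of the two (a small L1 value) is the convergence diagnostic of the
#' numerical bridge solution.
#'
#' @param fwd,bwd [trajectory_ensemble]s on the same time grid.
#' @param times Physical times at which to compare (matched to the nearest
#'   grid point; must lie on the shared grid).
#' @param bandwidth Optional KDE bandwidth (default: Silverman on the pooled
#'   samples, per time).
#' @param grid_n Grid size per axis.
#' @return A data frame with columns `t` and `l1`.
#' @export
marginal_consistency <- function(fwd, bwd, times, bandwidth = NULL, grid_n = 96) {
  stopifnot(inherits(fwd, "trajectory_ensemble"), inherits(bwd, "trajectory_ensemble"))
  if (length(fwd$times) != length(bwd$times) ||
      max(abs(fwd$times - bwd$times)) > 1e-9)
    stop("ensembles do not share a time grid")
  out <- data.frame(t = numeric(0), l1 = numeric(0))
  for (tt in times) {
    k <- which.min(abs(fwd$times - tt))
    if (abs(fwd$times[k] - tt) > 1e-6 * max(1, max(fwd$times)))
      stop("requested time ", tt, " is not on the shared grid")
    A <- slice_states(fwd, k)
    B <- slice_states(bwd, k)
    pool <- rbind(A, B)
    bw <- bandwidth %||%
      vapply(seq_len(ncol(pool)), function(j) silverman_bw(pool[, j]), numeric(1))
    lower <- apply(pool, 2, min) - 3 * bw
    upper <- apply(pool, 2, max) + 3 * bw
    gs <- list(lower = lower, upper = upper, n = grid_n)
    ka <- kde_density(A, gs, bw)
    kb <- kde_density(B, gs, bw)
    diffk <- ka; diffk$z <- abs(ka$z - kb$z)
    out <- rbind(out, data.frame(t = fwd$times[k], l1 = kde_integral(diffk)))
  }
  out
}

# Extract the n x d state matrix at time index k.
slice_states <- function(ens, k) {
  d <- dim(ens$states)[3]
  X <- ens$states[, k, , drop = TRUE]
  if (is.null(dim(X))) X <- matrix(X, ncol = d)
  X
}
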