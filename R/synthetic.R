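# Seeded synthetic-data generators: Gaussian marginal pairs for bridge smoke
# tests, a non-convex two-component target emulating a 2-D embedding of two
# cohorts (one connected initial cluster, a disconnected target), and jump
# series for tipping-detection unit tests.  Every generator is a pure
# function of its configuration and seed.

#' Gaussian marginal pair
#'
#' @param cfg List: `n` (samples per marginal), `d` (1 or 2), `mean0`,
#'   `sd0`, `mean1`, `sd1` (scalars or length-d vectors; sds are per-
#'   coordinate standard deviations), `seed`.
#' @return `list(rho0, rho1)` of n x d matrices.
#' @export
make_gaussian_pair <- function(cfg = list()) {
  n <- cfg$n %||% 1000L
  d <- cfg$d %||% 1L
  mean0 <- rep_len(cfg$mean0 %||% -2, d)
  mean1 <- rep_len(cfg$mean1 %||% 2, d)
  sd0 <- rep_len(cfg$sd0 %||% sqrt(0.1), d)
  sd1 <- rep_len(cfg$sd1 %||% sqrt(0.1), d)
  stopifnot(n >= 1)
  with_seed(cfg$seed, {
    rho0 <- sapply(seq_len(d), function(j) stats::rnorm(n, mean0[j], sd0[j]))
    rho1 <- sapply(seq_len(d), function(j) stats::rnorm(n, mean1[j], sd1[j]))
    list(rho0 = matrix(rho0, n, d), rho1 = matrix(rho1, n, d))
  })
}

#' Connected source with a non-convex two-component target
#'
#' Emulates a 2-D embedding in which one cohort forms a single connected
#' cluster and the other splits into two disjoint components, so that the
#' convex hull of the target contains a near-empty region (the geometry that
#' makes the optimal transport map discontinuous). Components are isotropic
#' blobs by default; `shape = "crescent"` bends each component into an arc.
#'
#' @param cfg List: `n` (total samples per marginal, default 5000), `seed`,
#'   `center0` (source center, default c(-2, 0)), `sd0` (source spread,
#'   default 0.3), `centers` (2 x 2 matrix of component centers, default
#'   rows (2, 1.5) and (2, -1.5)), `spreads` (per-component spread, default
#'   0.3), `weights` (component weights, default c(0.5, 0.5)),
#'   `shape` (`"blob"` or `"crescent"`).
#' @return `list(rho0, rho1, component)`: n x 2 matrices and the component
#'   label of each target sample. Errors if the two components are not
#'   disjoint (centers closer than 3 spreads).
#' @export
make_nonconvex_target <- function(cfg = list()) {
  n <- cfg$n %||% 5000L
  center0 <- cfg$center0 %||% c(-2, 0)
  sd0 <- cfg$sd0 %||% 0.3
  centers <- cfg$centers %||% rbind(c(2, 1.5), c(2, -1.5))
  spreads <- rep_len(cfg$spreads %||% 0.3, 2L)
  weights <- cfg$weights %||% c(0.5, 0.5)
  shape <- cfg$shape %||% "blob"
  stopifnot(n >= 1, length(weights) == 2L, all(weights > 0))
  weights <- weights / sum(weights)
  gap <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  if (gap < 3 * max(spreads)) stop("components not disjoint")
  with_seed(cfg$seed, {
    rho0 <- cbind(stats::rnorm(n, center0[1], sd0),
                  stats::rnorm(n, center0[2], sd0))
    comp <- stats::rbinom(n, 1L, weights[2]) + 1L
    pts <- matrix(NA_real_, n, 2L)
    for (k in 1:2) {
      idx <- which(comp == k)
      m <- length(idx)
      if (m == 0L) next
      if (shape == "crescent") {
        th <- stats::runif(m, -pi / 2, pi / 2)
        r <- 3 * spreads[k] + stats::rnorm(m, 0, spreads[k] / 2)
        pts[idx, ] <- cbind(centers[k, 1] + r * cos(th),
                            centers[k, 2] + r * sin(th))
      } else {
        pts[idx, ] <- cbind(stats::rnorm(m, centers[k, 1], spreads[k]),
                            stats::rnorm(m, centers[k, 2], spreads[k]))
      }
    }
    list(rho0 = rho0, rho1 = pts, component = comp)
  })
}

#' Non-convexity certificate of a two-component sample set
#'
#' Checks that the kernel density estimate at the midpoint between the two
#' component means is below `frac` of the density at the component modes.
#'
#' @param rho1 n x 2 target samples.
#' @param component Component labels (1/2).
#' @param frac Threshold fraction (default 0.1).
#' @return `TRUE`/`FALSE`.
#' @export
nonconvexity_certificate <- function(rho1, component, frac = 0.1) {
  X <- as_sample_matrix(rho1, "rho1")
  c1 <- colMeans(X[component == 1L, , drop = FALSE])
  c2 <- colMeans(X[component == 2L, , drop = FALSE])
  mid <- (c1 + c2) / 2
  k <- kde_density(X)
  at <- function(pt) {
    i <- which.min(abs(k$x[[1]] - pt[1])); j <- which.min(abs(k$x[[2]] - pt[2]))
    k$z[i, j]
  }
  at(mid) < frac * max(at(c1), at(c2))
}

#' Smooth baseline series with one injected jump
#'
#' Indicator-series-shaped fixture for tipping-detection tests: a linear
#' baseline plus optional noise, with a single jump of the given height at
#' the given step.
#'
#' @param cfg List: `n` (length, default 50), `jump_index` (step at which the
#'   jump occurs), `jump_height`, `slope` (baseline increment per step,
#'   default 0.01), `noise_sd` (default 0), `seed`.
#' @return An `indicator_series`-shaped data frame (`step`, `t`, `I`, `dI`,
#'   `a_inst`).
#' @export
make_jump_series <- function(cfg = list()) {
  n <- cfg$n %||% 50L
  j <- cfg$jump_index %||% 25L
  height <- cfg$jump_height %||% 1
  slope <- cfg$slope %||% 0.01
  noise_sd <- cfg$noise_sd %||% 0
  if (j < 1L || j >= n) stop("jump index out of range")
  with_seed(cfg$seed, {
    I <- slope * seq_len(n) + stats::rnorm(n, 0, noise_sd)
    # jump between step j and step j + 1, so the increment at step j spikes
    I[(j + 1L):n] <- I[(j + 1L):n] + height
    s <- data.frame(step = seq_len(n), t = seq_len(n) / n, I = I,
                    dI = c(abs(diff(I)), NA_real_), a_inst = NA_real_)
    class(s) <- c("indicator_series", "data.frame")
    s
  })
}
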