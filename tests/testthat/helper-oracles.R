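# Independent brute-force references used by the tests. These deliberately do
# not call the package's closed-form or bridge code paths.

# Log-domain Sinkhorn solution of the static entropic coupling between two
# 1-D densities discretized on fine grids, followed by Brownian-bridge mixing
# to obtain the time-t marginal moments. Stable down to small noise levels.
grid_sinkhorn_moments <- function(mu0, var0, mu1, var1, g, t_grid,
                                  ngrid = 400, span = 8, iters = 5000) {
  x <- seq(mu0 - span * sqrt(var0), mu0 + span * sqrt(var0), length.out = ngrid)
  y <- seq(mu1 - span * sqrt(var1), mu1 + span * sqrt(var1), length.out = ngrid)
  lp <- stats::dnorm(x, mu0, sqrt(var0), log = TRUE); lp <- lp - logsumexp(lp)
  lq <- stats::dnorm(y, mu1, sqrt(var1), log = TRUE); lq <- lq - logsumexp(lq)
  lK <- -outer(x, y, function(a, b) (a - b)^2) / (2 * g^2)
  row_lse <- function(M) {
    rm <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
    rm + log(rowSums(exp(M - rm)))
  }
  f <- rep(0, ngrid); h <- rep(0, ngrid)
  for (i in seq_len(iters)) {
    f <- lp - row_lse(sweep(lK, 2, h, "+"))
    h <- lq - row_lse(t(lK + f))
    if (i %% 25 == 0) {
      # stop when the row marginal is reproduced to near machine precision
      err <- max(abs(exp(row_lse(sweep(lK, 2, h, "+") + f)) - exp(lp)))
      if (err < 1e-14) break
    }
  }
  lPi <- lK + outer(f, h, "+")
  Pi <- exp(lPi - logsumexp(as.numeric(lPi)))
  res <- vapply(t_grid, function(t) {
    mt <- outer(x, y, function(a, b) (1 - t) * a + t * b)
    m1 <- sum(Pi * mt)
    m2 <- sum(Pi * mt^2) + g^2 * t * (1 - t)
    c(m1, m2 - m1^2)
  }, numeric(2))
  list(mean = res[1, ], var = res[2, ])
}

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

# Independent 2-D equilibrium refinement: minimize ||field||^2 by Nelder-Mead
# then high-precision BFGS, seeded from a coarse grid scan.
independent_equilibrium <- function(f, lower, upper, n_grid = 50) {
  g1 <- seq(lower[1], upper[1], length.out = n_grid)
  g2 <- seq(lower[2], upper[2], length.out = n_grid)
  grid <- as.matrix(expand.grid(g1, g2))
  nrm <- rowSums(f(grid)^2)
  obj <- function(x) sum(f(matrix(x, 1))^2)
  best <- grid[which.min(nrm), ]
  o <- stats::optim(best, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-16, maxit = 5000))
  o <- stats::optim(o$par, obj, method = "BFGS",
                    control = list(reltol = 1e-16, maxit = 1000))
  o$par
}

# Area of the convex hull of a 2-D point set (shoelace on chull vertices).
hull_area <- function(X) {
  idx <- grDevices::chull(X)
  P <- X[idx, , drop = FALSE]
  n <- nrow(P)
  j <- c(2:n, 1)
  abs(sum(P[, 1] * P[j, 2] - P[j, 1] * P[, 2])) / 2
}

# Seed scoping for test fixtures (restores the caller's RNG stream).
with_seed_test <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
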