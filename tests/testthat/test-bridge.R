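# Propagation, divergence, likelihood loss, KDE and the forward/backward
# consistency diagnostic.

test_that("zero-score forward propagation is Brownian with variance g^2 T", {
  g <- 0.5; T <- 2
  m <- bridge_model(schedule = noise_schedule("constant", g), T = T, N = 100, d = 1)
  ens <- propagate_forward(m, matrix(0, 100, 1), n_paths = 5000, seed = 1)
  incr <- ens$states[, 101, 1] - ens$states[, 1, 1]
  se <- g^2 * T * sqrt(2 / (5000 - 1))
  expect_lt(abs(stats::var(incr) - g^2 * T), 3 * se)
  expect_lt(abs(mean(incr)), 3 * g * sqrt(T) / sqrt(5000))
})

test_that("zero-score backward propagation grows variance toward t = 0", {
  g <- 0.6
  m <- bridge_model(schedule = noise_schedule("constant", g), T = 1, N = 80, d = 1)
  ens <- propagate_backward(m, matrix(0, 50, 1), n_paths = 4000, seed = 2)
  # Var(X_t - X_1) = g^2 (1 - t): check at t = 0 and mid-grid
  v0 <- stats::var(ens$states[, 1, 1])
  expect_lt(abs(v0 - g^2), 3 * g^2 * sqrt(2 / 3999))
  k <- 41  # t = 0.5
  vm <- stats::var(ens$states[, k, 1] - ens$states[, 81, 1])
  expect_lt(abs(vm - g^2 * 0.5), 3 * g^2 * 0.5 * sqrt(2 / 3999))
})

test_that("noise-free single-path propagation ignores the seed", {
  m <- bridge_model(schedule = noise_schedule("constant", 0), T = 1, N = 50, d = 2,
                    z_fwd = score_constant(c(1, -1)))
  a <- propagate_forward(m, matrix(c(0, 0), 1), n_paths = 1, seed = 1)
  b <- propagate_forward(m, matrix(c(0, 0), 1), n_paths = 1, seed = 999)
  expect_identical(a$states, b$states)
  expect_error(propagate_forward(m, matrix(0, 1, 1)), "dimension")
})

test_that("propagation with the closed-form score tracks the oracle marginals", {
  a <- gaussian_spec(-2, 0.1); b <- gaussian_spec(2, 0.4)
  g <- 0.5; n <- 5000
  m <- bridge_model(schedule = noise_schedule("constant", g), T = 1, N = 200, d = 1,
                    z_fwd = gaussian_bridge_score(a, b, g, "forward"),
                    z_bwd = gaussian_bridge_score(a, b, g, "backward"))
  r0 <- with_seed_test(31, matrix(stats::rnorm(n, -2, sqrt(0.1)), ncol = 1))
  ens <- propagate_forward(m, r0, n, seed = 11)
  cf <- gaussian_sb_closed_form(a, b, g, ens$times)
  mns <- colMeans(ens$states[, , 1])
  vrs <- apply(ens$states[, , 1], 2, stats::var)
  expect_lt(max(abs(mns - cf$mean) / sqrt(cf$var / n)), 3)
  expect_lt(max(abs(vrs - cf$var) / (cf$var * sqrt(2 / (n - 1)))), 3)
  # backward direction: t = 0 marginal moments recover rho0
  r1 <- with_seed_test(32, matrix(stats::rnorm(n, 2, sqrt(0.4)), ncol = 1))
  bwd <- propagate_backward(m, r1, n, seed = 12)
  expect_lt(abs(mean(bwd$states[, 1, 1]) + 2) / sqrt(0.1 / n), 4)
  expect_lt(abs(stats::var(bwd$states[, 1, 1]) - 0.1) / (0.1 * sqrt(2 / (n - 1))), 4)
})

test_that("divergence is exact on polynomial and linear fields and matches FD on MLPs", {
  A <- matrix(c(2, 1, -1, 3), 2, 2)
  lin <- function(t, X) X %*% t(A)
  X <- rbind(c(0.3, -0.7), c(1, 2), c(-2, 0.5))
  expect_equal(field_divergence(lin, 0.5, X), rep(sum(diag(A)), 3))
  expect_equal(field_divergence(score_constant(c(3, -4)), 0.2, X), rep(0, 3))
  sq <- function(t, X) cbind(X[, 1]^2, X[, 2]^2)
  expect_equal(field_divergence(sq, 0, matrix(c(1, 2), 1)), 6)
  # analytic MLP divergence (incl. the linear skip path) vs central differences
  f <- score_mlp(2, hidden = 16, init_scale = 0.5, seed = 4)
  f$W3 <- matrix(stats::rnorm(6, 0, 0.5), 2, 3)
  ana <- field_divergence(f, 0.3, X)
  num <- field_divergence(function(t, Y) sf_eval(f, t, Y), 0.3, X)
  expect_equal(ana, num, tolerance = 1e-6)
})

test_that("likelihood loss reduces to hand-computed values in degenerate settings", {
  g <- 0.7
  m <- bridge_model(schedule = noise_schedule("constant", g), T = 1, N = 20, d = 1)
  r0 <- with_seed_test(7, matrix(stats::rnorm(10, 0, 1), ncol = 1))
  ens <- propagate_forward(m, r0, 10, seed = 5)
  # zero scores, zero drift: only the terminal term survives
  term <- list(type = "logdensity", fn = function(X) stats::dnorm(X[, 1], log = TRUE))
  hand <- -mean(stats::dnorm(ens$states[, 21, 1], log = TRUE))
  expect_equal(likelihood_loss(m, ens, term), hand, tolerance = 1e-10)
  # a constant backward field adds only its quadratic part (divergence = 0)
  m2 <- m; m2$z_bwd <- score_constant(1.5)
  expect_equal(likelihood_loss(m2, ens, NULL), 0.5 * 1.5^2, tolerance = 1e-10)
  # doubling both scores quadruples the quadratic term on a frozen batch
  m3 <- m
  m3$z_fwd <- score_constant(0.8); m3$z_bwd <- score_constant(0.4)
  m4 <- m
  m4$z_fwd <- score_constant(1.6); m4$z_bwd <- score_constant(0.8)
  expect_equal(likelihood_loss(m4, ens, NULL), 4 * likelihood_loss(m3, ens, NULL),
               tolerance = 1e-10)
})

test_that("kernel density estimates integrate to one and match analytic densities", {
  x <- with_seed_test(9, matrix(stats::rnorm(5000), ncol = 1))
  k1 <- kde_density(x)
  expect_lt(abs(kde_integral(k1) - 1), 1e-2)
  # mode value within 15% of the standard normal density at 0
  i0 <- which.min(abs(k1$x[[1]]))
  expect_lt(abs(k1$z[i0] - stats::dnorm(0)) / stats::dnorm(0), 0.15)
  # 2-D: tight cluster peaks at the cluster mean
  xy <- with_seed_test(10, cbind(stats::rnorm(500, 2, 0.05), stats::rnorm(500, -1, 0.05)))
  k2 <- kde_density(xy)
  expect_lt(abs(kde_integral(k2) - 1), 1e-2)
  pk <- which(k2$z == max(k2$z), arr.ind = TRUE)
  expect_lt(abs(k2$x[[1]][pk[1]] - 2), 3 * k2$dx[1] + 0.05)
  expect_lt(abs(k2$x[[2]][pk[2]] + 1), 3 * k2$dx[2] + 0.05)
  expect_error(kde_density(matrix(1, 5, 1), bandwidth = 0), "bandwidth")
})

test_that("marginal consistency is zero on itself and small for equal-law ensembles", {
  m <- bridge_model(schedule = noise_schedule("constant", 0.5), T = 1, N = 40, d = 1)
  e1 <- propagate_forward(m, matrix(0, 50, 1), 1500, seed = 21)
  e2 <- propagate_forward(m, matrix(0, 50, 1), 1500, seed = 22)
  self <- marginal_consistency(e1, e1, times = c(0.5, 1))
  expect_equal(self$l1, c(0, 0))
  # equal-law ensembles: discrepancy at the Monte-Carlo noise floor, which we
  # estimate by splitting one ensemble in half
  half1 <- e1; half1$states <- e1$states[1:750, , , drop = FALSE]
  half2 <- e1; half2$states <- e1$states[751:1500, , , drop = FALSE]
  floor_est <- marginal_consistency(half1, half2, times = 1)$l1
  cross <- marginal_consistency(e1, e2, times = 1)$l1
  expect_lt(cross, 3 * floor_est)
  bad <- e2; bad$times <- e2$times * 2
  expect_error(marginal_consistency(e1, bad, times = 1), "time grid")
})
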