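# Semi-discrete optimal transport: cell decomposition, height optimization,
# cluster splitting, and the quadratic terminal attachment.

disk_samples <- function(n, seed = 1) {
  # uniform on the unit disk centered at the origin
  with_seed_test(seed, {
    r <- sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th))
  })
}

two_atoms <- target_atoms(rbind(c(1, 0), c(-1, 0)))

test_that("cell assignment is the support-plane argmax with low-index ties", {
  expect_equal(cell_assign(c(0.5, 0), two_atoms), 1L)
  expect_equal(cell_assign(c(-0.5, 0), two_atoms), 2L)
  # exactly equidistant: tie broken to the first atom
  expect_equal(cell_assign(c(0, 0.7), two_atoms), 1L)
  # raising h_2 enough forces assignment to atom 2
  x <- c(0.5, 0)
  margin <- sum(x * (two_atoms$Y[1, ] - two_atoms$Y[2, ]))
  expect_equal(cell_assign(x, two_atoms, h = c(0, margin + 0.01)), 2L)
})

test_that("cell masses are conserved and symmetric on the centered disk", {
  X <- disk_samples(20000)
  expect_equal(cell_masses(X, target_atoms(matrix(c(0.3, 0.4), 1))), 1)
  om <- cell_masses(X, two_atoms)
  expect_lt(max(abs(om - 0.5)), 0.02)
  for (h in list(c(0.3, -0.2), c(-1, 2))) {
    expect_equal(sum(cell_masses(X, two_atoms, h)), 1)
  }
})

test_that("the energy gradient is the mass mismatch, confirmed by finite differences", {
  X <- disk_samples(4000, seed = 3)
  atoms <- target_atoms(rbind(c(1, 0), c(-1, 0)), nu = c(0.7, 0.3))
  h <- c(0.2, 0)
  eg <- ot_energy_grad(X, atoms, h)
  expect_equal(eg$gradient, cell_masses(X, atoms, h) - atoms$nu)
  eps <- 0.05
  for (i in 1:2) {
    e_i <- rep(0, 2); e_i[i] <- eps
    fd <- (ot_energy_grad(X, atoms, h + e_i, n_quad = 256)$value -
             ot_energy_grad(X, atoms, h, n_quad = 256)$value) / eps
    expect_lt(abs(fd - eg$gradient[i]), 0.03)
  }
  # additive-constant invariance: E(h + c 1) = E(h) after weight normalization
  e_shift <- ot_energy_grad(X, atoms, h + 0.37)
  expect_equal(e_shift$value, eg$value, tolerance = 1e-10)
  expect_equal(cell_assign(X, atoms, h + 0.37), cell_assign(X, atoms, h))
})

test_that("height optimization makes the map measure-preserving", {
  X <- disk_samples(20000, seed = 5)
  # symmetric problem: balanced weights need no height offset
  h_sym <- solve_heights(X, two_atoms)
  expect_lt(max(abs(h_sym)), 0.05)
  # asymmetric weights: solved cells carry the prescribed masses
  atoms <- target_atoms(rbind(c(1, 0), c(-1, 0)), nu = c(0.75, 0.25))
  h <- solve_heights(X, atoms)
  expect_lt(max(abs(cell_masses(X, atoms, h) - atoms$nu)), 0.02)
  expect_equal(h[2], 0)  # gauge
  # single atom: nothing to optimize
  expect_equal(solve_heights(X, target_atoms(matrix(c(0, 0), 1))), 0)
})

test_that("target-cluster splitting partitions the source by cluster mass", {
  dat <- make_nonconvex_target(list(n = 4000, seed = 11, weights = c(0.6, 0.4)))
  res <- split_by_target_clusters(dat$rho0, dat$rho1, 2)
  w0 <- vapply(res$pairs, function(pr) nrow(pr$rho0) / nrow(dat$rho0), numeric(1))
  w1 <- vapply(res$pairs, function(pr) nrow(pr$rho1) / nrow(dat$rho1), numeric(1))
  expect_lt(max(abs(w0 - w1)), 0.03)
  # disjoint and exhaustive over the source samples
  expect_equal(sum(vapply(res$pairs, function(pr) nrow(pr$rho0), integer(1))),
               nrow(dat$rho0))
  expect_setequal(unique(res$assignment0), 1:2)
  # trivial split
  res1 <- split_by_target_clusters(dat$rho0, dat$rho1, 1)
  expect_equal(length(res1$pairs), 1L)
  expect_equal(nrow(res1$pairs[[1]]$rho0), nrow(dat$rho0))
})

test_that("cluster terminal loss is the hand-computed mean squared distance", {
  X1 <- rbind(c(0, 0), c(1, 2), c(-1, 1))
  Y <- rbind(c(0, 0), c(2, 2), c(1, 1))
  expect_equal(cluster_terminal_loss(Y, Y), 0)
  hand <- (0 + (1^2 + 0^2) + (2^2 + 0^2)) / 3
  expect_equal(cluster_terminal_loss(X1, Y), hand, tolerance = 1e-12)
  # doubling the residuals quadruples the loss
  expect_equal(cluster_terminal_loss(Y + 2 * (X1 - Y), Y),
               4 * cluster_terminal_loss(X1, Y))
  expect_error(cluster_terminal_loss(X1, Y[1:2, ]), "shape")
})
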