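test_that("confinement radius reproduces the bead volume fraction", {
  expect_equal(confinement_radius_from_fraction(1, 0.125), 1.0)
  expect_equal(confinement_radius_from_fraction(510, 0.10),
               (510 / 0.10)^(1 / 3) / 2)
  r1 <- confinement_radius_from_fraction(100, 0.1)
  expect_equal(confinement_radius_from_fraction(200, 0.1) / r1, 2^(1 / 3))
  expect_error(confinement_radius_from_fraction(10, 0), "fraction")
  expect_error(confinement_radius_from_fraction(10, 1.2), "fraction")
})

test_that("contact indicator is a smooth unit step around the cutoff", {
  expect_equal(contact_indicator(1.8, 1.8, 5), 0.5)
  expect_gte(contact_indicator(0, 1.8, 5), 0.999)
  r <- seq(0, 4, by = 0.05)
  expect_true(all(diff(contact_indicator(r)) <= 0))
  expect_true(all(contact_indicator(r) >= 0 & contact_indicator(r) <= 1))
})

test_that("bias field zeroes the diagonal and adjacent bands", {
  set.seed(2)
  a <- matrix(rnorm(64), 8, 8); a <- a + t(a)
  b <- bias_field(a)
  expect_equal(diag(b), rep(0, 8))
  expect_equal(unname(b[cbind(1:7, 2:8)]), rep(0, 7))
  expect_equal(unclass(b), t(unclass(b)))
  expect_error(bias_field(matrix(1:16, 4, 4)), "symmetric")
  expect_error(stage_potential("x", homopolymer_params(5), bias_field(8)),
               "chain length")
})

test_that("straight confined chain has zero bond, angle and wall energy", {
  p <- homopolymer_params(5, confinement_radius = 10)
  x <- cbind(seq(-2, 2), 0, 0)
  ef <- homopolymer_energy_forces(x, p)
  expect_equal(unname(ef$components[c("bond", "angle", "wall")]), c(0, 0, 0))
  # a lone bead pushed radially past the wall pays the half-harmonic cost
  d <- 0.3
  p1 <- homopolymer_params(1, confinement_radius = 2)
  ef1 <- homopolymer_energy_forces(matrix(c(2 + d, 0, 0), 1, 3), p1)
  expect_equal(unname(ef1$components[["wall"]]),
               0.5 * p1$wall_stiffness * d^2)
})

test_that("soft-core repulsion stays bounded by its cap", {
  p <- homopolymer_params(2)
  overlapped <- matrix(c(0, 0, 0, 1e-4, 0, 0), 2, 3, byrow = TRUE)
  ef <- homopolymer_energy_forces(overlapped, p)
  expect_lte(unname(ef$components[["softcore"]]), p$softcore_cap + 1e-9)
  expect_true(all(is.finite(ef$forces)))
})

test_that("analytic forces match central finite differences", {
  set.seed(9)
  X <- random_chain(10, seed = 9)
  p <- homopolymer_params(10, confinement_radius = 1.5)
  b <- bias_field({m <- matrix(rnorm(100), 10, 10); (m + t(m)) / 2})
  st <- stage_potential("t", p, b)
  ef <- total_energy_forces(X, st)
  h <- 1e-6
  num <- matrix(0, 10, 3)
  for (i in 1:10) for (d in 1:3) {
    Xp <- X; Xm <- X
    Xp[i, d] <- X[i, d] + h; Xm[i, d] <- X[i, d] - h
    num[i, d] <- -(total_energy_forces(Xp, st)$energy -
                     total_energy_forces(Xm, st)$energy) / (2 * h)
  }
  expect_lt(max(abs(num - ef$forces)) / max(abs(ef$forces)), 1e-5)
})

test_that("bias energy follows the indicator and splits off additively", {
  X <- random_chain(6, seed = 3, scale = 2)
  p <- homopolymer_params(6)
  a <- matrix(0, 6, 6)
  expect_equal(bias_energy_forces(X, bias_field(a), p)$energy, 0)
  # single pair at exactly the cutoff contributes alpha * 1/2
  Y <- matrix(0, 6, 3)
  Y[, 1] <- c(0, 1, 2, 3, 4, 5)
  Y[5, ] <- Y[2, ] + c(1.8, 0, 0) # pair (2,5) at r_c
  Y[5, 1] <- Y[2, 1] + 1.8
  a[2, 5] <- a[5, 2] <- 2
  eb <- bias_energy_forces(Y, bias_field(a), p)
  # other pairs of Y sit on a line; only (2,5) has alpha != 0
  expect_equal(eb$energy, 1.0, tolerance = 1e-12)
  # total = homopolymer + bias at random configurations
  st <- stage_potential("t", p, bias_field(a))
  for (s in 1:5) {
    Z <- random_chain(6, seed = 20 + s)
    tot <- total_energy_forces(Z, st)
    hh <- homopolymer_energy_forces(Z, p)
    bb <- bias_energy_forces(Z, bias_field(a), p)
    expect_equal(tot$energy, hh$energy + bb$energy)
    expect_equal(tot$forces, hh$forces + bb$forces)
  }
})

test_that("energy is invariant under rigid motions (wall disabled)", {
  p <- homopolymer_params(8, wall_stiffness = 0)
  b <- bias_field({set.seed(4); m <- matrix(rnorm(64), 8, 8); (m + t(m)) / 2})
  st <- stage_potential("t", p, b)
  X <- random_chain(8, seed = 5)
  e0 <- total_energy_forces(X, st)
  R <- random_rotation(6)
  Xr <- X %*% t(R) + matrix(c(3, -1, 2), 8, 3, byrow = TRUE)
  er <- total_energy_forces(Xr, st)
  expect_equal(er$energy, e0$energy, tolerance = 1e-10)
  # net force and net torque vanish
  expect_lt(max(abs(colSums(e0$forces))), 1e-9)
  torque <- colSums(cbind(
    X[, 2] * e0$forces[, 3] - X[, 3] * e0$forces[, 2],
    X[, 3] * e0$forces[, 1] - X[, 1] * e0$forces[, 3],
    X[, 1] * e0$forces[, 2] - X[, 2] * e0$forces[, 1]))
  expect_lt(max(abs(torque)), 1e-9)
})

test_that("stage archives round-trip through text", {
  p <- homopolymer_params(7, angle_stiffness = 1.5)
  b <- bias_field({set.seed(8); m <- matrix(rnorm(49), 7, 7); (m + t(m)) / 2})
  st <- stage_potential("Mid G1", p, b)
  f <- tempfile()
  write_stage_potential(st, f)
  back <- read_stage_potential(f)
  expect_identical(back$label, "Mid G1")
  expect_equal(unclass(back$params), unclass(p))
  expect_equal(unclass(back$bias), unclass(b))
})
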