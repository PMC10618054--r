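# physics checks for the BAOAB integrator at the production settings

test_that("a minimum-energy configuration at T = 0 is a fixed point", {
  p <- homopolymer_params(2, softcore_strength = 0, angle_stiffness = 0,
                          wall_stiffness = 0)
  st <- stage_potential("min", p)
  X <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  V <- matrix(0, 2, 3)
  s <- langevin_settings(temperature = 0)
  for (i in 1:100) {
    out <- langevin_step(X, V, st, s)
    X2 <- out$conf; V <- out$velocities
  }
  expect_equal(X2, X, tolerance = 1e-14)
})

test_that("energy does not grow at T = 0 (integrator sanity)", {
  p <- homopolymer_params(10, wall_stiffness = 0)
  st <- stage_potential("drift", p)
  X <- initial_chain(10, p, seed = 3)
  s <- langevin_settings(temperature = 0, seed = 1)
  e0 <- homopolymer_energy_forces(X, p)$energy
  tr <- run_trajectory(X, st, s, duration = 5, record_stride = 5,
                       velocities = matrix(0, 10, 3))  # 10^4 steps
  eT <- homopolymer_energy_forces(matrix(tr$frames[, , 2], ncol = 3),
                                  p)$energy +
    0.5 * sum(tr$final_velocities^2)
  expect_lte(eT, e0 + 1e-4 * 10)
})

test_that("frame recording arithmetic and the sampling window flag", {
  p <- homopolymer_params(3)
  st <- stage_potential("s", p)
  tr <- run_trajectory(initial_chain(3, p, seed = 1), st,
                       langevin_settings(seed = 5), duration = 1,
                       record_stride = 0.5)
  expect_equal(tr$times, c(0, 0.5, 1.0))
  expect_equal(dim(tr$frames)[3], 3L)
  # annealed run: second half flagged for sampling
  tr2 <- run_trajectory(initial_chain(3, p, seed = 1), st,
                        langevin_settings(seed = 5),
                        schedule = annealing_schedule(ramp_duration = 2,
                                                      total_duration = 8),
                        record_stride = 1)
  expect_equal(tr2$sampling_start, 4)
  expect_equal(dim(sampling_frames(tr2))[3], 5L)  # t = 4..8
})

test_that("the annealing ramp is linear between its stated endpoints", {
  p <- homopolymer_params(2)
  st <- stage_potential("s", p)
  tr <- run_trajectory(initial_chain(2, p, seed = 2), st,
                       langevin_settings(seed = 9),
                       schedule = annealing_schedule(),  # 4 -> 1 over 250 tau
                       record_stride = 25)
  at <- function(t) tr$temperatures[which.min(abs(tr$times - t))]
  expect_equal(at(0), 4)
  expect_equal(at(125), 2.5, tolerance = 1e-3)
  expect_equal(at(250), 1)
  expect_equal(at(600), 1)
})

test_that("trajectories are deterministic in the seed", {
  p <- homopolymer_params(5)
  st <- stage_potential("s", p)
  x0 <- initial_chain(5, p, seed = 1)
  t1 <- run_trajectory(x0, st, langevin_settings(seed = 42), duration = 1,
                       record_stride = 0.25)
  t2 <- run_trajectory(x0, st, langevin_settings(seed = 42), duration = 1,
                       record_stride = 0.25)
  t3 <- run_trajectory(x0, st, langevin_settings(seed = 43), duration = 1,
                       record_stride = 0.25)
  expect_identical(t1$frames, t2$frames)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("free-bead diffusion obeys the Einstein relation", {
  # single unconfined bead: MSD / (6 t) -> T / gamma = 0.1 sigma^2/tau
  p <- homopolymer_params(1, softcore_strength = 0,
                          confinement_radius = Inf, wall_stiffness = 0)
  st <- stage_potential("free", p)
  tr <- run_trajectory(matrix(0, 1, 3), st, langevin_settings(seed = 7),
                       duration = 1500, record_stride = 1)
  lags <- c(5, 10, 20)
  D <- vapply(lags, function(L) {
    mean(msd(tr, L, remove_com = FALSE)) / (6 * L)
  }, numeric(1))
  expect_equal(mean(D), 0.1, tolerance = 0.1)
})

test_that("a harmonic degree of freedom equipartitions at T/2", {
  # two beads bonded with r0 = 0: E = k/2 |r12|^2, separable per axis
  k <- 100
  p <- homopolymer_params(2, bond_length = 0, bond_stiffness = k,
                          softcore_strength = 0, angle_stiffness = 0,
                          wall_stiffness = 0)
  st <- stage_potential("spring", p)
  x0 <- matrix(c(0, 0, 0, 0.1, 0, 0), 2, 3, byrow = TRUE)
  tr <- run_trajectory(x0, st, langevin_settings(seed = 11), duration = 300,
                       record_stride = 0.05)
  burn <- tr$times > 5
  rel <- tr$frames[1, , burn] - tr$frames[2, , burn]  # 3 x frames
  per_axis <- 0.5 * k * rowMeans(rel^2)
  expect_equal(unname(per_axis), rep(0.5, 3), tolerance = 0.05)
})

test_that("replica orchestration derives seeds deterministically", {
  p <- homopolymer_params(4)
  st <- stage_potential("s", p)
  x0 <- initial_chain(4, p, seed = 2)
  r1 <- run_replicas(x0, st, langevin_settings(), n_replicas = 2,
                     base_seed = 3, duration = 1, record_stride = 0.5)
  r2 <- run_replicas(x0, st, langevin_settings(), n_replicas = 2,
                     base_seed = 3, duration = 1, record_stride = 0.5)
  expect_false(identical(r1[[1]]$frames, r1[[2]]$frames))
  expect_identical(r1[[1]]$frames, r2[[1]]$frames)
  expect_identical(attr(r1, "seeds"), attr(r2, "seeds"))
  ens <- pool_ensemble(r1, window = FALSE)
  expect_equal(dim(ens)[3], 2 * 3)
  # every trajectory carries its manifest
  expect_equal(r1[[2]]$manifest$seed, attr(r1, "seeds")[2])
})
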