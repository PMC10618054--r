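test_that("gyration tensor matches the centred covariance oracle", {
  expect_equal(gyration_tensor(matrix(1, 4, 3) * c(2, 2, 2, 2)),
               matrix(0, 3, 3))
  two <- matrix(c(1, 0, 0, -1, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(gyration_tensor(two), diag(c(1, 0, 0)))
  X <- random_chain(20, seed = 12)
  T_ <- gyration_tensor(X)
  oracle <- cov(X) * (19 / 20)     # 1/N convention
  expect_equal(T_, unname(oracle))
  ev <- eigen(T_, symmetric = TRUE)$values
  expect_equal(sort(ev, decreasing = TRUE), geometry(X)$eigenvalues)
})

test_that("asphericity hits the sphere and rod limits exactly", {
  octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  g <- geometry(octa)
  expect_equal(g$Delta, 0)
  rod <- cbind(seq(0, 9), 0, 0)
  expect_equal(geometry(rod)$Delta, 1)
  # two beads separated by d: Rg = d/2
  d <- 3.7
  expect_equal(geometry(matrix(c(0, 0, 0, d, 0, 0), 2, 3,
                               byrow = TRUE))$Rg, d / 2)
  # identity Rg^2 = tr T = sum of eigenvalues on random configurations
  for (s in 1:5) {
    X <- random_chain(15, seed = 30 + s)
    g <- geometry(X)
    expect_equal(g$Rg^2, sum(diag(gyration_tensor(X))))
    expect_equal(g$Rg^2, sum(g$eigenvalues))
    expect_gte(g$Delta, 0); expect_lte(g$Delta, 1)
  }
})

test_that("free-energy landscape is a min-shifted -log histogram", {
  rec <- data.frame(Rg = c(rep(1, 3), rep(2, 1)), Delta = c(rep(0.1, 3),
                                                            rep(0.9, 1)))
  fel <- free_energy_landscape(rec, bins = 2)
  vals <- sort(fel$F[!is.na(fel$F)])
  expect_equal(vals, c(0, log(3)))   # occupancies 0.75 / 0.25
  rec2 <- data.frame(Rg = c(1, 2), Delta = c(0.1, 0.9))
  fel2 <- free_energy_landscape(rec2, bins = 2)
  expect_equal(unname(fel2$F[!is.na(fel2$F)]), c(0, 0))
  # brute-force histogram agreement on random records
  set.seed(44)
  rec3 <- data.frame(Rg = runif(200, 1, 3), Delta = runif(200))
  fel3 <- free_energy_landscape(rec3, bins = 5)
  ix <- cut(rec3$Rg, fel3$Rg_breaks, include.lowest = TRUE, labels = FALSE)
  iy <- cut(rec3$Delta, fel3$Delta_breaks, include.lowest = TRUE,
            labels = FALSE)
  cnt <- table(factor(ix, 1:5), factor(iy, 1:5))
  ref <- -log(cnt / 200)
  ref[!is.finite(ref)] <- NA
  ref <- ref - min(ref, na.rm = TRUE)
  expect_equal(unname(fel3$F), unname(matrix(ref, 5, 5)), tolerance = 1e-12)
})

test_that("alignment removes rigid-body motion and is idempotent", {
  X <- random_chain(12, seed = 2)
  copies <- lapply(1:6, function(k) {
    X %*% t(random_rotation(100 + k)) +
      matrix(rnorm(3, 0, 4), 12, 3, byrow = TRUE)
  })
  al <- align_ensemble(copies)
  spread <- apply(al$frames, 3, function(f)
    sqrt(mean((matrix(f, ncol = 3) - al$mean)^2)))
  expect_true(all(spread < 1e-8))
  # the mean equals the template up to a rigid motion
  expect_lt(sqrt(mean((.cc_kabsch_rotate(al$mean, X) -
                         sweep(X, 2, colMeans(X)))^2)), 1e-8)
  al2 <- align_ensemble(al$frames)
  expect_equal(al2$frames, al$frames, tolerance = 1e-7)
})

test_that("alignment is at least as good as any single random rotation", {
  set.seed(77)
  ens <- lapply(1:5, function(k) random_chain(10, seed = 50 + k))
  al <- align_ensemble(ens)
  ssd <- sum((al$frames - array(al$mean, dim(al$frames)))^2)
  for (k in 1:5) {
    perturbed <- al$frames
    Xk <- matrix(perturbed[, , k], ncol = 3) %*% t(random_rotation(60 + k))
    perturbed[, , k] <- Xk
    mean_p <- apply(perturbed, c(1, 2), mean)
    ssd_p <- sum((perturbed - array(mean_p, dim(perturbed)))^2)
    expect_gte(ssd_p, ssd - 1e-9)
  }
})

test_that("fluctuation matrix: closed-form two-member ensemble and guards", {
  X <- random_chain(8, seed = 21)
  al_id <- align_ensemble(list(X, X, X))
  M0 <- fluctuation_matrix(al_id)
  expect_equal(unclass(M0), matrix(0, 8, 8), tolerance = 1e-14,
               ignore_attr = TRUE)
  # hand-built two-member ensemble: M_ij = u_i . u_j
  set.seed(3)
  u <- matrix(rnorm(24, 0, 0.1), 8, 3)
  al <- structure(list(frames = as_ensemble(list(X + u, X - u)),
                       mean = X, iterations = 0),
                  class = "aligned_ensemble")
  M <- fluctuation_matrix(al)
  expect_equal(unclass(M), tcrossprod(u), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(diag(M), rowSums(u^2), tolerance = 1e-12)
  # raw (unaligned) input is refused
  expect_error(fluctuation_matrix(as_ensemble(list(X, X + u))), "align")
})

test_that("fluctuation matrix ignores rigid motion applied pre-alignment", {
  set.seed(5)
  base <- lapply(1:8, function(k) random_chain(10, seed = 70 + k) * 0.3 +
                   cbind(seq_len(10), 0, 0))
  M1 <- fluctuation_matrix(align_ensemble(base))
  moved <- lapply(seq_along(base), function(k) {
    base[[k]] %*% t(random_rotation(200 + k)) +
      matrix(rnorm(3, 0, 10), 10, 3, byrow = TRUE)
  })
  M2 <- fluctuation_matrix(align_ensemble(moved))
  expect_equal(unclass(M2), unclass(M1), tolerance = 1e-6)
})

test_that("delta_M is an antisymmetric elementwise difference", {
  set.seed(6)
  A <- matrix(rnorm(25), 5, 5); A <- A + t(A)
  B <- matrix(rnorm(25), 5, 5); B <- B + t(B)
  expect_equal(delta_M(A, A), matrix(0, 5, 5))
  expect_equal(delta_M(A, B), -delta_M(B, A))
  expect_equal(delta_M(A, B), A - B)
  expect_error(delta_M(A, matrix(0, 4, 4)), "shape")
})

test_that("MSD is zero for static and rigidly translating trajectories", {
  X <- random_chain(6, seed = 31)
  frames <- array(0, c(6, 3, 5))
  for (k in 1:5) frames[, , k] <- X
  tr <- structure(list(frames = frames, times = 0:4 * 1.0,
                       sampling_start = 0), class = "cc_trajectory")
  expect_equal(msd(tr, 2), rep(0, 6))
  for (k in 1:5) frames[, , k] <- X + (k - 1) * 2  # ballistic drift
  tr$frames <- frames
  expect_equal(msd(tr, 2), rep(0, 6), tolerance = 1e-14)
  expect_error(msd(tr, 10), "lag")
})
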