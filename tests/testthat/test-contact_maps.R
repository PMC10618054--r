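test_that("region bin arithmetic uses the inclusive-start convention", {
  r <- genomic_region("chr1", 20.5, 71.4, 100)
  expect_identical(r$locus_count, 510L)
  expect_identical(genomic_region("chrX", 0, 0.3, 100)$locus_count, 4L)
  expect_error(genomic_region("chr1", 5, 5, 100), "start_mb")
})

test_that("reading dense and triple dialects validates inputs", {
  reg3 <- genomic_region("chrT", 0, 0.2, 100)
  f <- tempfile()
  writeLines(c("0 0 0", "0 0 0", "0 0 0"), f)
  m <- read_contact_map(f, reg3)
  expect_true(all(m$P == 0))

  writeLines("0 1 0.5", f)
  m <- read_contact_map(f, reg3)
  expect_equal(m$P[1, 2], 0.5)
  expect_equal(m$P[2, 1], 0.5)
  expect_equal(sum(m$P), 1.0)

  # a 509-side dense file is rejected for the 510-locus production region
  reg510 <- genomic_region("chr1", 20.5, 71.4, 100)
  big <- matrix(0, 509, 509)
  write.table(big, f, row.names = FALSE, col.names = FALSE)
  expect_error(read_contact_map(f, reg510, format = "dense"), "509")

  writeLines(c("0 1 0.5", "0 7 0.1"), f)
  expect_error(read_contact_map(f, reg3), "out of range")
  writeLines("0 1 -0.5", f)
  expect_error(read_contact_map(f, reg3), "negative")
  writeLines(c("0 0 0 0", "0 0 0 0", "0 0 0 0"), f)
  expect_error(read_contact_map(f, reg3, format = "dense"), "not square")
})

test_that("write/read round-trips are exact across dialects", {
  m <- random_map(12, seed = 42)
  f1 <- tempfile(); f2 <- tempfile()
  write_contact_map(m, f1, "dense")
  write_contact_map(m, f2, "triples")
  back1 <- read_contact_map(f1, m$region)
  back2 <- read_contact_map(f2, m$region)
  expect_identical(back1$P, m$P)
  expect_identical(back2$P, back1$P)
})

test_that("normalize_adjacent anchors the adjacent band at exactly 1", {
  n <- 10
  P <- matrix(0, n, n); diag(P) <- 1
  P[cbind(1:(n - 1), 2:n)] <- 0.2
  P[cbind(2:n, 1:(n - 1))] <- 0.2
  P[1, 8] <- P[8, 1] <- 0.1
  m <- normalize_adjacent(contact_map(P, genomic_region("chrT", 0, 0.9, 100)))
  expect_identical(unname(m$P[cbind(1:(n - 1), 2:n)]), rep(1, n - 1))
  expect_equal(m$P[1, 8], 0.5)   # divide-by-anchor oracle
  expect_true(all(m$P <= 1) && all(m$P >= 0))
  # idempotence
  m2 <- normalize_adjacent(m)
  expect_identical(m2$P, m$P)
  # zero anchor is an error
  Z <- matrix(0, 5, 5); diag(Z) <- 1
  expect_error(normalize_adjacent(
    contact_map(Z, genomic_region("chrT", 0, 0.4, 100))), "anchor")
})

test_that("expected_by_distance matches a brute-force double loop", {
  m <- random_map(6, seed = 7)
  e <- expected_by_distance(m)
  for (s in 1:5) {
    acc <- c()
    for (i in 1:(6 - s)) acc <- c(acc, m$P[i, i + s])
    expect_equal(unname(e[s]), mean(acc))
  }
  # a distance-only map reproduces its generating function
  tm <- toeplitz_map(8)
  expect_equal(unname(expected_by_distance(tm)), 1 / (1:7))
})

test_that("enhanced contacts: distance-only input gives flat zero log-ratios", {
  tm <- toeplitz_map(20)
  em <- enhanced_contacts(tm, 500)   # 5-locus coarse bins
  expect_true(all(abs(em$log2_ratio[!is.na(em$log2_ratio)]) < 1e-10))
})

test_that("enhanced contacts: an enriched block is located and scale-invariant", {
  m <- toeplitz_map(20)
  P <- m$P
  block_r <- 1:5; block_c <- 11:15   # coarse cell (1, 3) at 500 kb
  P[block_r, block_c] <- P[block_r, block_c] * 6
  P[block_c, block_r] <- t(P[block_r, block_c])
  m2 <- contact_map(P, m$region)
  em <- enhanced_contacts(m2, 500)
  off <- em$log2_ratio
  off[lower.tri(off, diag = TRUE)] <- NA
  hot <- which(off > 0.5, arr.ind = TRUE)
  expect_equal(unname(hot[1, ]), c(1, 3))
  expect_equal(nrow(hot), 1L)
  # hand-summed block
  Pd <- P; diag(Pd) <- 0
  expect_equal(em$P_obs[1, 3], sum(Pd[1:5, 11:15]))
  # global scaling leaves the ratio untouched
  em2 <- enhanced_contacts(contact_map(P / 2, m$region), 500)
  expect_equal(em2$log2_ratio, em$log2_ratio)
  expect_error(enhanced_contacts(m2, 333), "integer multiple")
})

test_that("insulation profile matches a brute-force sliding window", {
  m <- random_map(30, seed = 3)
  w <- 5
  prof <- insulation_profile(m, 500)
  raw <- rep(NA_real_, 30)
  for (i in (w + 1):(30 - w)) {
    acc <- c()
    for (a in (i - w):(i - 1)) for (b in (i + 1):(i + w))
      acc <- c(acc, m$P[a, b])
    raw[i] <- mean(acc)
  }
  expect_equal(prof$raw, raw)
  expect_equal(prof$scores, log2(raw / mean(raw, na.rm = TRUE)))
  expect_identical(which(is.na(prof$scores)), c(1:w, (30 - w + 1):30))
  # uniform map scores are all zero
  u <- contact_map(matrix(0.4, 30, 30) + diag(0.6, 30),
                   genomic_region("chrT", 0, 2.9, 100))
  pu <- insulation_profile(u, 500)
  expect_true(all(abs(pu$scores[!is.na(pu$scores)]) < 1e-12))
  expect_error(insulation_profile(random_map(8), 500), "window")
})

test_that("two perfect blocks give a unique insulation minimum at the split", {
  n <- 30; b <- 15
  P <- matrix(0, n, n)
  P[1:b, 1:b] <- 0.8
  P[(b + 1):n, (b + 1):n] <- 0.8
  diag(P) <- 1
  m <- contact_map(P, genomic_region("chrT", 0, 2.9, 100))
  prof <- insulation_profile(m, 500)
  expect_equal(which.min(prof$scores), b)
})

test_that("TAD boundary calling: monotone, V-shaped and planted profiles", {
  mk <- function(v) structure(list(scores = v, raw = 2^v, window_loci = 1),
                              class = "insulation_profile")
  expect_identical(tad_boundaries(mk(seq(-1, 1, length.out = 9))), integer(0))
  v <- c(1, .5, 0, -1, 0, .5, 1)
  expect_identical(tad_boundaries(mk(v)), 4L)
  expect_identical(tad_boundaries(mk(v), strength_threshold = 5), integer(0))
  # planted TADs in a synthetic map
  sm <- make_interphase_map(synthetic_spec(seed = 5))
  found <- tad_boundaries(insulation_profile(sm$map, 500))
  expect_length(found, length(sm$tad_boundaries))
  expect_true(all(abs(found - sm$tad_boundaries) <= 1))
})

test_that("compartment PC1 recovers a planted checkerboard up to the convention", {
  n <- 8
  lab <- rep(c(1, -1), 4)
  M <- outer(lab, lab) * 0.7
  em <- structure(list(log2_ratio = M, P_obs = abs(M) + 0.1,
                       P_exp = matrix(1, n, n), bin_size = 1),
                  class = "enhanced_map")
  cp <- compartment_profile(em)
  expect_equal(abs(cor(cp$pc1, lab)), 1, tolerance = 1e-10)
  # negated input resolves to the same orientation under the convention
  em2 <- em; em2$log2_ratio <- -M
  cp2 <- compartment_profile(em2)
  expect_equal(abs(sum(cp$pc1 * cp2$pc1)), 1, tolerance = 1e-10)
  # degenerate input
  em0 <- em; em0$log2_ratio <- matrix(0, n, n)
  expect_error(compartment_profile(em0), "degenerate")
})
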