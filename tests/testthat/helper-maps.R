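# shared fixture builders: everything is generated in code at test time

# random symmetric contact matrix with unit diagonal, entries in [0, 1]
random_map <- function(n, seed = 1, normalized = FALSE) {
  set.seed(seed)
  P <- matrix(runif(n * n, 0.01, 0.9), n, n)
  P <- (P + t(P)) / 2
  diag(P) <- 1
  m <- contact_map(P, genomic_region("chrT", 0, (n - 1) / 10, 100))
  if (normalized) normalize_adjacent(m) else m
}

# map whose entries depend only on |i - j|
toeplitz_map <- function(n, fun = function(s) ifelse(s == 0, 1, 1 / s)) {
  d <- abs(row(diag(n)) - col(diag(n)))
  P <- matrix(fun(d), n, n)
  contact_map(P, genomic_region("chrT", 0, (n - 1) / 10, 100))
}

# small random chain configurations
random_chain <- function(n, seed = 1, scale = 1.2) {
  set.seed(seed)
  matrix(rnorm(3 * n, 0, scale), n, 3)
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
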