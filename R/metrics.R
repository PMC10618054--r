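#' Gyration tensor of a configuration
#'
#' The centred second-moment tensor `T = (1/N) sum (r_i - rbar)(r_i - rbar)^T`
#' (unit masses). Its trace is the squared radius of gyration and its
#' eigenvalues are the squared extensions along the principal axes.
#'
#' @param conf N x 3 coordinate matrix.
#' @return Symmetric positive semidefinite 3 x 3 matrix (sigma^2).
#' @export
gyration_tensor <- function(conf) {
  check_configuration(conf)
  X <- sweep(conf, 2, colMeans(conf))
  crossprod(X) / nrow(X)
}

#' Gyration geometry: radius of gyration and asphericity
#'
#' From the gyration tensor eigenvalues `lambda_1 >= lambda_2 >= lambda_3`:
#' `Rg = sqrt(lambda_1 + lambda_2 + lambda_3)` and the aspheric quantity
#' `Delta = (3/2) sum_k (lambda_k - mean(lambda))^2 / (tr T)^2`, which is 0
#' for an isotropic (sphere-like) configuration and 1 in the rod limit.
#'
#' @param conf N x 3 coordinate matrix.
#' @return A list of class `geometry_record` with fields `Rg`, `Delta`,
#'   `eigenvalues` (decreasing).
#' @export
geometry <- function(conf) {
  T_ <- gyration_tensor(conf)
  lam <- sort(eigen(T_, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  lam[lam < 0] <- 0  # numerical guard; T is PSD
  tr <- sum(lam)
  Delta <- if (tr > 0) 1.5 * sum((lam - tr / 3)^2) / tr^2 else NA_real_
  structure(list(Rg = sqrt(tr), Delta = Delta, eigenvalues = lam),
            class = "geometry_record")
}

#' Geometry table for an ensemble
#'
#' @param ensemble N x 3 x M array or list of configurations.
#' @return data.frame with one row per structure: `Rg`, `Delta`.
#' @export
geometry_records <- function(ensemble) {
  ensemble <- as_ensemble(ensemble)
  recs <- lapply(seq_len(dim(ensemble)[3]), function(k)
    geometry(matrix(ensemble[, , k], ncol = 3)))
  data.frame(Rg = vapply(recs, `[[`, numeric(1), "Rg"),
             Delta = vapply(recs, `[[`, numeric(1), "Delta"))
}

#' Free-energy landscape over (Rg, Delta)
#'
#' A 2D histogram of the geometry records converted to reduced free energy
#' `-ln p` (thermal units at the sampling temperature), with the minimum
#' shifted to zero and empty bins masked (`NA`).
#'
#' @param records data.frame with `Rg` and `Delta` columns (see
#'   [geometry_records()]).
#' @param bins Number of bins per axis (default 25), or a list with
#'   `Rg`/`Delta` break vectors.
#' @return A list of class `free_energy_landscape`: `F` (matrix, rows = Rg
#'   bins), `Rg_breaks`, `Delta_breaks`.
#' @export
free_energy_landscape <- function(records, bins = 25) {
  stopifnot(nrow(records) >= 1)
  if (is.list(bins) && !is.null(bins$Rg)) {
    bx <- bins$Rg; by <- bins$Delta
  } else {
    pad <- function(v) {
      r <- range(v)
      if (diff(r) == 0) r <- r + c(-0.5, 0.5)
      seq(r[1] - 1e-9, r[2] + 1e-9, length.out = bins + 1)
    }
    bx <- pad(records$Rg); by <- pad(records$Delta)
  }
  ix <- cut(records$Rg, bx, include.lowest = TRUE, labels = FALSE)
  iy <- cut(records$Delta, by, include.lowest = TRUE, labels = FALSE)
  counts <- matrix(0, length(bx) - 1, length(by) - 1)
  for (k in seq_along(ix))
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  p <- counts / sum(counts)
  F_ <- -log(p)
  F_[!is.finite(F_)] <- NA
  F_ <- F_ - min(F_, na.rm = TRUE)
  structure(list(F = F_, Rg_breaks = bx, Delta_breaks = by),
            class = "free_energy_landscape")
}

#' Align a structural ensemble to its iterative mean
#'
#' Removes rigid-body motion: every structure is centred, rotated by the
#' optimal least-squares (Kabsch) rotation onto the running mean structure,
#' and the mean is recomputed; the loop repeats until the mean moves by less
#' than `tol`. The converged mean is the reference for fluctuation
#' analysis -- the ensemble average, not any single representative.
#'
#' @param ensemble N x 3 x M array or list, M >= 2.
#' @param tol Convergence threshold on mean displacement (sigma).
#' @param max_iter Iteration cap.
#' @return A list of class `aligned_ensemble`: `frames` (aligned array),
#'   `mean` (N x 3), `iterations`.
#' @export
align_ensemble <- function(ensemble, tol = 1e-8, max_iter = 100) {
  ens <- as_ensemble(ensemble)
  m <- dim(ens)[3]
  if (m < 2) stop("need at least 2 structures to align")
  for (k in seq_len(m)) {
    X <- matrix(ens[, , k], ncol = 3)
    ens[, , k] <- sweep(X, 2, colMeans(X))
  }
  ref <- matrix(ens[, , 1], ncol = 3)
  for (it in seq_len(max_iter)) {
    for (k in seq_len(m))
      ens[, , k] <- .cc_kabsch_rotate(matrix(ens[, , k], ncol = 3), ref)
    new_mean <- apply(ens, c(1, 2), mean)
    shift <- sqrt(mean((new_mean - ref)^2))
    ref <- new_mean
    if (it > 1 && shift < tol) break
  }
  structure(list(frames = ens, mean = ref, iterations = it),
            class = "aligned_ensemble")
}

#' Fluctuation (coherent-motion) matrix
#'
#' `M_ij = < delta r_i . delta r_j >` with `delta r_i = r_i - <r_i>`, taken
#' over an aligned ensemble; positive entries mark loci moving coherently,
#' negative entries anticorrelated motion. Alignment matters -- the input
#' must come from [align_ensemble()].
#'
#' @param aligned An `aligned_ensemble`.
#' @return Symmetric N x N matrix of class `fluctuation_matrix` (sigma^2)
#'   with an `ensemble_size` attribute.
#' @export
fluctuation_matrix <- function(aligned) {
  if (!inherits(aligned, "aligned_ensemble"))
    stop("fluctuation_matrix requires an aligned ensemble; call align_ensemble first")
  ens <- aligned$frames
  m <- dim(ens)[3]
  n <- dim(ens)[1]
  M <- matrix(0, n, n)
  for (d in 1:3) {
    D <- matrix(ens[, d, ], n, m) - aligned$mean[, d]
    M <- M + tcrossprod(D) / m
  }
  structure((M + t(M)) / 2, class = c("fluctuation_matrix", "matrix", "array"),
            ensemble_size = m)
}

#' Difference of fluctuation matrices
#'
#' `Delta M_ij(t) = M_ij(t) - M_ij(0)`: how coherent motion at time `t`
#' after a landscape switch differs from the pre-switch ensemble.
#'
#' @param M_t,M_0 Equal-shape fluctuation matrices.
#' @return Elementwise difference matrix.
#' @export
delta_M <- function(M_t, M_0) {
  if (!all(dim(M_t) == dim(M_0))) stop("shape mismatch")
  unclass(M_t) - unclass(M_0)
}

#' Per-locus mean squared displacement at a time lag
#'
#' Time-averaged squared displacement of each locus over all frame pairs
#' separated by `lag`, after removing per-frame centre-of-mass drift.
#'
#' @param traj A `cc_trajectory`.
#' @param lag Time lag (tau); matched to the frame grid.
#' @param remove_com Subtract the per-frame centre of mass (default TRUE);
#'   disable to measure absolute diffusion, e.g. of a free bead.
#' @return Numeric vector (length N) of MSD values (sigma^2).
#' @export
msd <- function(traj, lag, remove_com = TRUE) {
  times <- traj$times
  dt_frame <- if (length(times) > 1) times[2] - times[1] else
    stop("need at least 2 frames")
  k <- as.integer(round(lag / dt_frame))
  if (k < 1 || k >= length(times)) stop("lag outside the trajectory span")
  ens <- traj$frames
  n <- dim(ens)[1]; m <- dim(ens)[3]
  if (remove_com) {
    for (f in seq_len(m)) {
      X <- matrix(ens[, , f], ncol = 3)
      ens[, , f] <- sweep(X, 2, colMeans(X))
    }
  }
  acc <- numeric(n)
  for (f in seq_len(m - k)) {
    d <- matrix(ens[, , f + k] - ens[, , f], ncol = 3)
    acc <- acc + rowSums(d^2)
  }
  acc / (m - k)
}
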