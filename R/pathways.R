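#' Fit a 2-component PCA model over profile vectors
#'
#' Profiles (insulation scores or flattened upper-triangle enhanced maps)
#' are the feature vectors; masked features -- positions undefined (`NA`) in
#' any profile of the fitting set -- are dropped from the feature space
#' globally rather than imputed. The model keeps the feature mean and the
#' top-2 orthonormal axes, with a deterministic sign convention: each axis
#' is oriented so its largest-magnitude loading is positive.
#'
#' @param fitting_set List (or rows of a matrix) of equal-length numeric
#'   profiles; at least 3.
#' @return A list of class `profile_pca`: `mean`, `axes` (features x 2),
#'   `explained_variance` (length 2), `feature_mask` (logical kept-feature
#'   flags over the original length).
#' @export
fit_profile_pca <- function(fitting_set) {
  X <- if (is.matrix(fitting_set)) fitting_set else do.call(rbind,
                                                            fitting_set)
  if (nrow(X) < 3) stop("need at least 3 profiles to fit")
  keep <- apply(X, 2, function(col) all(is.finite(col)))
  if (sum(keep) < 2) stop("fewer than 2 usable features after masking")
  Xk <- X[, keep, drop = FALSE]
  pc <- prcomp(Xk, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2 || pc$sdev[1] < 1e-12)
    stop("fitting set is degenerate (all profiles identical)")
  axes <- pc$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(mean = pc$center, axes = axes,
                 explained_variance = ev[1:2], feature_mask = keep),
            class = "profile_pca")
}

#' Project a profile series into a fitted PC plane
#'
#' @param model A `profile_pca` from [fit_profile_pca()].
#' @param series List of profiles (or matrix rows) of the model's original
#'   feature length; optionally named/timed via the `times` argument.
#' @param times Optional numeric times or stage labels, one per profile.
#' @return A data.frame of class `pathway_projection` with columns `time`,
#'   `PC1`, `PC2`.
#' @export
project_series <- function(model, series, times = NULL) {
  stopifnot(inherits(model, "profile_pca"))
  X <- if (is.matrix(series)) series else do.call(rbind, series)
  if (ncol(X) != length(model$feature_mask))
    stop("profile length does not match the fitted model")
  Xk <- X[, model$feature_mask, drop = FALSE]
  Z <- sweep(Xk, 2, model$mean) %*% model$axes
  out <- data.frame(time = if (is.null(times)) seq_len(nrow(X)) else times,
                    PC1 = Z[, 1], PC2 = Z[, 2])
  class(out) <- c("pathway_projection", "data.frame")
  out
}

#' Linear-interpolation baseline between two contact maps
#'
#' The null pathway against which simulated transitions are judged: contact
#' maps `P(s) = (1 - s) P_A + s P_B` at `n_steps` evenly spaced mixing
#' fractions, each passed through the chosen observable. Interpolation of
#' normalized maps preserves the unit adjacent band, so the interpolates
#' remain valid maps.
#'
#' @param map_A,map_B [contact_map()]s on the same region.
#' @param n_steps Number of interpolation points including endpoints
#'   (default 11).
#' @param observable `"insulation"` (default) or `"enhanced"`; extra
#'   arguments in `...` reach the observable.
#' @param ... Passed to [insulation_profile()] or [enhanced_contacts()].
#' @return A list of class `profile_series`: `profiles` (matrix, one row
#'   per step), `s` (mixing fractions), `maps` (the interpolated maps),
#'   `observable`.
#' @export
linear_interpolation_path <- function(map_A, map_B, n_steps = 11,
                                      observable = c("insulation",
                                                     "enhanced"), ...) {
  observable <- match.arg(observable)
  stopifnot(inherits(map_A, "contact_map"), inherits(map_B, "contact_map"),
            n_steps >= 2)
  if (!identical(map_A$region[c("locus_count", "resolution_kb")],
                 map_B$region[c("locus_count", "resolution_kb")]))
    stop("maps are on different regions")
  s <- seq(0, 1, length.out = n_steps)
  maps <- lapply(s, function(f)
    contact_map((1 - f) * map_A$P + f * map_B$P, map_A$region,
                normalized = map_A$normalized && map_B$normalized))
  profiles <- do.call(rbind, lapply(maps, profile_of, observable, ...))
  structure(list(profiles = profiles, s = s, maps = maps,
                 observable = observable),
            class = "profile_series")
}

profile_of <- function(map, observable, ...) {
  if (observable == "insulation") {
    insulation_profile(map, ...)$scores
  } else {
    em <- enhanced_contacts(map, ...)$log2_ratio
    em[upper.tri(em, diag = TRUE)]
  }
}

#' Deviation of a simulated pathway from an interpolation baseline
#'
#' The mean, over the simulated path's points, of the minimum Euclidean
#' distance to the interpolated polyline in the PC plane, normalized by the
#' separation between the interpolated endpoints. 0 means the simulated
#' transition tracks the linear baseline; large values mean a nonlinear
#' route.
#'
#' @param simulated,interpolated `pathway_projection`s in the same fitted
#'   model.
#' @return Scalar deviation score (dimensionless).
#' @export
path_deviation <- function(simulated, interpolated) {
  A <- as.matrix(interpolated[, c("PC1", "PC2")])
  S <- as.matrix(simulated[, c("PC1", "PC2")])
  L <- sqrt(sum((A[nrow(A), ] - A[1, ])^2))
  if (L < 1e-12) stop("degenerate baseline: coincident endpoints")
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- max(0, min(1, t))
    sqrt(sum((p - (a + t * ab))^2))
  }
  d <- vapply(seq_len(nrow(S)), function(i) {
    min(vapply(seq_len(nrow(A) - 1), function(j)
      seg_dist(S[i, ], A[j, ], A[j + 1, ]), numeric(1)))
  }, numeric(1))
  mean(d) / L
}
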