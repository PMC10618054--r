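#' Cluster a structural ensemble by aligned RMSD
#'
#' Average-linkage agglomerative clustering on the pairwise Kabsch-aligned
#' RMSD matrix, cut at a distance threshold (sigma). Deterministic for a
#' given input order; permuting the input permutes labels but not the
#' partition.
#'
#' @param ensemble N x 3 x M array or list, M >= 1.
#' @param distance_threshold Tree cut height (sigma; default 0.8, below the
#'   typical pairwise RMSD of an equilibrium ensemble so genuinely distinct
#'   conformational families separate rather than lumping into one cluster).
#' @return A list of class `cluster_set`: `assignments` (integer per
#'   structure, clusters numbered by decreasing population), `populations`
#'   (fractions summing to 1), `medoids` (structure index per cluster),
#'   `rmsd` (pairwise matrix).
#' @export
cluster_ensemble <- function(ensemble, distance_threshold = 0.8) {
  ens <- as_ensemble(ensemble)
  m <- dim(ens)[3]
  if (m == 1) {
    return(structure(list(assignments = 1L, populations = 1,
                          medoids = 1L, rmsd = matrix(0, 1, 1)),
                     class = "cluster_set"))
  }
  D <- .cc_pairwise_rmsd(ens)
  hc <- hclust(as.dist(D), method = "average")
  raw <- cutree(hc, h = distance_threshold)
  # renumber by decreasing population, ties by lowest member index
  tab <- table(raw)
  first <- vapply(names(tab), function(l) min(which(raw == as.integer(l))),
                  integer(1))
  ord <- order(-as.integer(tab), first)
  relabel <- integer(length(tab))
  relabel[as.integer(names(tab))[ord]] <- seq_along(tab)
  assignments <- relabel[raw]
  populations <- as.numeric(table(assignments)) / m
  medoids <- vapply(seq_along(populations), function(cl) {
    members <- which(assignments == cl)
    if (length(members) == 1) return(members)
    members[which.min(rowMeans(D[members, members, drop = FALSE]))]
  }, integer(1))
  structure(list(assignments = assignments, populations = populations,
                 medoids = medoids, rmsd = D),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d structures in %d clusters; top populations: %s\n",
              length(x$assignments), length(x$populations),
              paste(sprintf("%.3f", head(x$populations, 5)), collapse = ", ")))
  invisible(x)
}

#' Select initial structures from an ensemble's clusters
#'
#' From every cluster whose population exceeds `min_population` (the
#' production protocol uses 0.2% of the ensemble), take the `per_cluster`
#' structures nearest the cluster medoid (the production protocol takes 2).
#' Clusters smaller than `per_cluster` contribute all their members.
#'
#' @param ensemble The clustered N x 3 x M array (or list).
#' @param clusters A `cluster_set` from [cluster_ensemble()].
#' @param min_population Population fraction a cluster must exceed
#'   (default 0.002).
#' @param per_cluster Structures per qualifying cluster (default 2).
#' @return List of N x 3 matrices with a `source_index` attribute.
#' @export
select_initials <- function(ensemble, clusters, min_population = 0.002,
                            per_cluster = 2) {
  stopifnot(inherits(clusters, "cluster_set"),
            min_population >= 0, min_population < 1, per_cluster >= 1)
  ens <- as_ensemble(ensemble)
  qualifying <- which(clusters$populations > min_population)
  if (!length(qualifying)) stop("no cluster exceeds the population threshold")
  picked <- integer(0)
  for (cl in qualifying) {
    members <- which(clusters$assignments == cl)
    med <- clusters$medoids[cl]
    d <- clusters$rmsd[members, med]
    take <- members[order(d, members)][seq_len(min(per_cluster,
                                                   length(members)))]
    picked <- c(picked, take)
  }
  out <- ensemble_list(ens[, , picked, drop = FALSE])
  attr(out, "source_index") <- picked
  out
}

#' Switch the energy landscape and collect relaxation trajectories
#'
#' The landscape-switching step: each initial structure, equilibrated under
#' the source stage potential, continues at constant temperature under the
#' target stage potential from t = 0 -- an instantaneous potential swap with
#' no re-thermalization. Velocities are drawn from the Maxwell--Boltzmann
#' distribution at the pre-switch temperature (statistically identical to
#' carrying them over from an equilibrated source run). Frames are recorded
#' at a regular stride; the named checkpoints are snapped to the frame grid.
#'
#' @param initials List of N x 3 matrices (see [select_initials()]).
#' @param source,target [stage_potential()]s calibrated for the same chain
#'   length.
#' @param settings A [langevin_settings()]; relaxation runs at its
#'   (constant) temperature, default 1 epsilon.
#' @param duration Relaxation length (tau; default 1000).
#' @param checkpoints Named observation times (tau; default 1, 10, 100,
#'   1000).
#' @param record_stride Frame stride (tau); must divide the checkpoints'
#'   spacing reasonably (default 0.5).
#' @param base_seed Base seed for the per-trajectory seeds.
#' @return A list of class `switching_run`: `trajectories`, `source_label`,
#'   `target_label`, `checkpoints`, `initials`.
#' @export
switch_and_relax <- function(initials, source, target,
                             settings = langevin_settings(),
                             duration = 1000,
                             checkpoints = c(1, 10, 100, 1000),
                             record_stride = 0.5, base_seed = 1) {
  stopifnot(inherits(source, "stage_potential"),
            inherits(target, "stage_potential"))
  if (source$params$n_beads != target$params$n_beads)
    stop("source and target potentials are for different chain lengths")
  if (is.matrix(initials)) initials <- list(initials)
  if (any(vapply(initials, nrow, integer(1)) != target$params$n_beads))
    stop("initial structures do not match the potentials' chain length")
  checkpoints <- checkpoints[checkpoints <= duration + 1e-9]
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(initials))
  trajs <- vector("list", length(initials))
  for (k in seq_along(initials)) {
    s <- settings
    s$seed <- seeds[k]
    set.seed(seeds[k])
    vel <- mb_velocities(nrow(initials[[k]]), settings$temperature)
    trajs[[k]] <- run_trajectory(initials[[k]], target, s,
                                 duration = duration,
                                 record_stride = record_stride,
                                 velocities = vel)
  }
  structure(list(trajectories = trajs, source_label = source$label,
                 target_label = target$label, checkpoints = checkpoints,
                 initials = initials, duration = duration),
            class = "switching_run")
}

#' @export
print.switching_run <- function(x, ...) {
  cat(sprintf(
    "<switching_run> %s -> %s: %d trajectories over %g tau, checkpoints %s\n",
    x$source_label, x$target_label, length(x$trajectories), x$duration,
    paste(x$checkpoints, collapse = "/")))
  invisible(x)
}

#' Time-resolved ensemble from a switching run
#'
#' One structure per trajectory: the recorded frame nearest time `t`.
#'
#' @param run A `switching_run`.
#' @param t Time (tau) within the run's duration.
#' @return N x 3 x R array (R = number of trajectories).
#' @export
time_resolved_ensemble <- function(run, t) {
  stopifnot(inherits(run, "switching_run"))
  if (!length(run$trajectories)) stop("empty switching run")
  if (t < 0 || t > run$duration + 1e-9) stop("t outside the run duration")
  parts <- lapply(run$trajectories, function(traj) {
    k <- which.min(abs(traj$times - t))
    matrix(traj$frames[, , k], ncol = 3)
  })
  as_ensemble(parts)
}
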