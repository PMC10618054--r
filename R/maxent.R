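#' Estimate contact probabilities from a structural ensemble
#'
#' The simulated contact probability is the ensemble mean of the smooth
#' contact indicator over all bead pairs, followed by the unit-adjacent
#' normalization so simulated and experimental maps share the same
#' convention.
#'
#' @param ensemble N x 3 x M array (or list of N x 3 matrices).
#' @param params A [homopolymer_params()] supplying `contact_cutoff`, `eta`.
#' @param region Optional [genomic_region()]; a synthetic 1-Mb-per-bead
#'   region is fabricated when absent.
#' @param normalize Apply [normalize_adjacent()] (default TRUE).
#' @return A [contact_map()].
#' @export
estimate_contact_probabilities <- function(ensemble, params, region = NULL,
                                           normalize = TRUE) {
  ensemble <- as_ensemble(ensemble)
  n <- dim(ensemble)[1]
  if (dim(ensemble)[3] < 1) stop("empty ensemble")
  P <- .cc_ensemble_contacts(ensemble, params$contact_cutoff, params$eta)
  if (is.null(region)) region <- synthetic_region(n)
  m <- contact_map(P, region)
  if (normalize) normalize_adjacent(m) else m
}

as_ensemble <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (is.matrix(x)) x <- list(x)
  if (!is.list(x) || !length(x)) stop("empty ensemble")
  n <- nrow(x[[1]])
  if (any(vapply(x, nrow, integer(1)) != n))
    stop("inconsistent chain lengths in ensemble")
  out <- array(0, c(n, 3, length(x)))
  for (k in seq_along(x)) out[, , k] <- x[[k]]
  out
}

ensemble_list <- function(ens) {
  lapply(seq_len(dim(ens)[3]), function(k) matrix(ens[, , k], ncol = 3))
}

synthetic_region <- function(n_loci, resolution_kb = 100) {
  genomic_region("chrS", 0, (n_loci - 1) * resolution_kb / 1000,
                 resolution_kb)
}

#' One maximum-entropy bias update
#'
#' Proportional fixed-point correction: for every pair beyond the adjacent
#' band, `alpha_ij <- alpha_ij + lr (P_sim - P_target)`, clamped to
#' `[-alpha_max, alpha_max]`. Over-formed contacts (`P_sim > P_target`) gain
#' positive coupling, which penalizes the contact energetically; starved
#' contacts gain negative (attractive) coupling. The excluded bands stay
#' exactly zero.
#'
#' @param bias Current [bias_field()].
#' @param P_sim Simulated [contact_map()].
#' @param P_target Target [contact_map()].
#' @param learning_rate Step size (epsilon per probability unit; default 2).
#' @param alpha_max Clamp bound (epsilon; default 10).
#' @return Updated [bias_field()].
#' @export
update_alpha <- function(bias, P_sim, P_target, learning_rate = 2,
                         alpha_max = 10) {
  stopifnot(inherits(P_sim, "contact_map"), inherits(P_target, "contact_map"))
  if (any(dim(bias) != dim(P_sim$P)) || any(dim(bias) != dim(P_target$P)))
    stop("shape mismatch between bias and maps")
  if (any(is.na(P_sim$P)) || any(is.na(P_target$P)))
    stop("NaN in contact map")
  a <- unclass(bias) + learning_rate * (P_sim$P - P_target$P)
  a[a > alpha_max] <- alpha_max
  a[a < -alpha_max] <- -alpha_max
  bias_field(a)  # re-zeroes diagonal and adjacent bands
}

offdiag_mask <- function(n) abs(row(diag(n)) - col(diag(n))) >= 2

map_error <- function(P_sim, P_target) {
  mask <- offdiag_mask(nrow(P_sim$P)) & upper.tri(P_sim$P)
  d <- P_sim$P[mask] - P_target$P[mask]
  c(mae = mean(abs(d)),
    pearson = suppressWarnings(cor(P_sim$P[mask], P_target$P[mask])))
}

#' Calibrate a stage potential against a target contact map
#'
#' The maximum-entropy loop: starting from the bare homopolymer (or a warm
#'-start bias), each iteration runs annealed replica trajectories under the
#' current stage potential, estimates the simulated contact map from the
#' sampling-window frames, records the mean absolute error and Pearson
#' correlation against the target over the off-band upper triangle, and
#' applies [update_alpha()]. Iteration stops when the MAE reaches `tol` or
#' after `max_iter` rounds. If the MAE increases three times in a row the
#' learning rate is halved (once more on repeat, then the loop aborts with
#' its history).
#'
#' @param target Normalized target [contact_map()].
#' @param params A [homopolymer_params()] for the chain; length must match
#'   the target side.
#' @param settings A [langevin_settings()].
#' @param schedule An [annealing_schedule()]; desk-scale runs shorten it.
#' @param n_replicas Annealed replicas per iteration (default 8).
#' @param max_iter Maximum iterations (default 20).
#' @param tol MAE convergence tolerance (default 0.02).
#' @param learning_rate,alpha_max Passed to [update_alpha()].
#' @param record_stride Frame stride in tau; chosen so each replica
#'   contributes many sampling-window frames.
#' @param base_seed Seed governing initial structures and all replicas.
#' @param init_bias Optional warm-start [bias_field()].
#' @param ema_weight Weight of the current iteration in the exponentially
#'   weighted moving average of the simulated map (default 0.5). Averaging
#'   across iterations pools sampling noise away near the fixed point
#'   without extra simulation; 1 disables it.
#' @param verbose Print per-iteration errors.
#' @return A list of class `calibration_state`: `stage` (calibrated
#'   [stage_potential()]), `P_sim`, `ensemble`, `history` (data.frame of
#'   iteration, mae, pearson, learning_rate), `converged`.
#' @export
calibrate <- function(target, params, settings = langevin_settings(),
                      schedule = annealing_schedule(ramp_duration = 15,
                                                    total_duration = 60),
                      n_replicas = 8, max_iter = 20, tol = 0.02,
                      learning_rate = 2, alpha_max = 10,
                      record_stride = 0.5, base_seed = 1,
                      init_bias = NULL, ema_weight = 0.5, verbose = FALSE) {
  stopifnot(inherits(target, "contact_map"))
  if (!target$normalized)
    stop("target map must be normalized (see normalize_adjacent)")
  n <- nrow(target$P)
  if (params$n_beads != n) stop("params chain length does not match target")
  bias <- if (is.null(init_bias)) bias_field(n) else bias_field(init_bias)

  set.seed(base_seed)
  init_seeds <- sample.int(.Machine$integer.max - 1L, n_replicas + 1L)
  initials <- lapply(init_seeds[-1], function(s) initial_chain(n, params, s))

  history <- data.frame(iteration = integer(0), mae = numeric(0),
                        pearson = numeric(0), learning_rate = numeric(0))
  lr <- learning_rate
  rising <- 0L
  halved <- 0L
  P_sim <- NULL; ensemble <- NULL
  for (it in seq_len(max_iter)) {
    stage <- stage_potential("calibrating", params, bias)
    trajs <- run_replicas(initials, stage, settings, schedule = schedule,
                          n_replicas = n_replicas,
                          base_seed = init_seeds[1] %% 100000L + it,
                          record_stride = record_stride)
    ensemble <- pool_ensemble(trajs, window = TRUE)
    P_iter <- estimate_contact_probabilities(ensemble, params,
                                             region = target$region)
    P_sim <- if (is.null(P_sim)) P_iter else
      contact_map(ema_weight * P_iter$P + (1 - ema_weight) * P_sim$P,
                  target$region, normalized = TRUE)
    err <- map_error(P_sim, target)
    history <- rbind(history, data.frame(iteration = it, mae = err[["mae"]],
                                         pearson = err[["pearson"]],
                                         learning_rate = lr))
    if (verbose)
      message(sprintf("iter %2d: MAE = %.4f  r = %.4f  lr = %.3g",
                      it, err[["mae"]], err[["pearson"]], lr))
    if (err[["mae"]] <= tol) break
    if (it >= 4 && all(diff(tail(history$mae, 4)) > 0)) {
      rising <- rising + 1L
      if (halved >= 2) {
        warning("calibration diverging; aborting with history")
        break
      }
      lr <- lr / 2
      halved <- halved + 1L
      if (verbose) message("MAE rising; learning rate halved to ", lr)
    }
    if (it < max_iter)
      bias <- update_alpha(bias, P_sim, target, lr, alpha_max)
    # warm restarts: next iteration starts from current ensemble structures
    m <- dim(ensemble)[3]
    pick <- round(seq(1, m, length.out = n_replicas))
    initials <- ensemble_list(ensemble[, , pick, drop = FALSE])
  }
  final <- map_error(P_sim, target)
  structure(list(stage = stage_potential("calibrated", params, bias),
                 P_sim = P_sim, ensemble = ensemble, history = history,
                 converged = final[["mae"]] <= tol,
                 mae = final[["mae"]], pearson = final[["pearson"]]),
            class = "calibration_state")
}

#' @export
print.calibration_state <- function(x, ...) {
  cat(sprintf(
    "<calibration_state> %d iterations, MAE = %.4f, Pearson r = %.4f (%s)\n",
    nrow(x$history), x$mae, x$pearson,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}
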