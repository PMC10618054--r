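#' Langevin dynamics settings
#'
#' Reduced-unit Langevin parameters: the production convention is a time
#' step of 0.0005 tau, a friction coefficient of 10 / tau, unit mass, and
#' temperature in epsilon (Boltzmann constant absorbed), so the free-bead
#' diffusion coefficient is `D = T / friction`.
#'
#' @param timestep Integration step (tau; default 0.0005).
#' @param friction Friction coefficient (1/tau; default 10).
#' @param temperature Thermostat temperature (epsilon; default 1).
#' @param seed Integer RNG seed, or `NULL` to leave the RNG stream alone.
#' @return A list of class `langevin_settings`.
#' @export
langevin_settings <- function(timestep = 0.0005, friction = 10,
                              temperature = 1, seed = NULL) {
  stopifnot(timestep > 0, friction > 0, temperature >= 0)
  structure(list(timestep = timestep, friction = friction,
                 temperature = temperature, seed = seed),
            class = "langevin_settings")
}

#' Simulated-annealing schedule
#'
#' Sampling runs anneal from a hot start to the sampling temperature: the
#' production protocol reduces the temperature from 4 epsilon to 1 epsilon
#' linearly over the first 250 tau of a 1000 tau trajectory, holds it there,
#' and samples the second half (500-1000 tau). Desk-scale runs shrink both
#' durations proportionally.
#'
#' @param T_start Initial temperature (epsilon; default 4).
#' @param T_end Final temperature (epsilon; default 1).
#' @param ramp_duration Linear ramp length (tau; default 250).
#' @param total_duration Trajectory length (tau; default 1000).
#' @return A list of class `annealing_schedule`.
#' @export
annealing_schedule <- function(T_start = 4, T_end = 1,
                               ramp_duration = 250, total_duration = 1000) {
  stopifnot(ramp_duration > 0, ramp_duration <= total_duration,
            T_start >= T_end)
  structure(list(T_start = T_start, T_end = T_end,
                 ramp_duration = ramp_duration,
                 total_duration = total_duration),
            class = "annealing_schedule")
}

#' Grow an initial chain configuration
#'
#' A self-avoiding-ish random walk with unit steps grown inside the
#' confinement sphere (new beads are rejected when they fall outside 95% of
#' the wall radius or within 0.9 sigma of a previous bead, with a capped
#' number of retries), followed by a short capped steepest-descent
#' relaxation. Used for cold starts of the first calibration round.
#'
#' @param n_beads Chain length.
#' @param params A [homopolymer_params()].
#' @param seed Optional RNG seed.
#' @return N x 3 coordinate matrix.
#' @export
initial_chain <- function(n_beads, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- min(params$confinement_radius, 1e3) * 0.95
  X <- matrix(0, n_beads, 3)
  for (i in seq_len(n_beads)[-1]) {
    for (try in 1:60) {
      u <- rnorm(3)
      cand <- X[i - 1, ] + params$bond_length * u / sqrt(sum(u^2))
      if (sqrt(sum(cand^2)) > R) next
      if (i > 2) {
        d2 <- rowSums((X[seq_len(i - 2), , drop = FALSE] -
                         matrix(cand, i - 2, 3, byrow = TRUE))^2)
        if (min(d2) < 0.81 && try < 60) next
      }
      break
    }
    X[i, ] <- cand
  }
  .cc_minimize(X, unclass(params), 500L, 0.05)
}

mb_velocities <- function(n_beads, temperature) {
  matrix(rnorm(3 * n_beads, sd = sqrt(temperature)), n_beads, 3)
}

#' Advance one Langevin step
#'
#' One BAOAB update of positions and velocities at the settings'
#' temperature. Deterministic given the RNG stream position.
#'
#' @param conf N x 3 coordinates.
#' @param velocities N x 3 velocities.
#' @param stage A [stage_potential()].
#' @param settings A [langevin_settings()].
#' @return List with `conf` and `velocities`.
#' @export
langevin_step <- function(conf, velocities, stage, settings) {
  stopifnot(all(is.finite(conf)), all(is.finite(velocities)))
  out <- .cc_run_langevin(conf, velocities, unclass(stage$params),
                          unclass(stage$bias), max(abs(stage$bias)) > 0,
                          settings$timestep, settings$friction,
                          settings$temperature, settings$temperature, 0L,
                          1L, 1L)
  list(conf = matrix(out$frames[, , 2], ncol = 3),
       velocities = out$final_velocities)
}

#' Run a Langevin trajectory
#'
#' Integrates the chain under a stage potential, either at constant
#' temperature or under an [annealing_schedule()] (linear ramp, then hold).
#' Frames are recorded at the stride, starting from the initial
#' configuration. With an annealing schedule the second half of the run is
#' flagged as the sampling window.
#'
#' @param initial N x 3 starting coordinates.
#' @param stage A [stage_potential()].
#' @param settings A [langevin_settings()]; its `seed` (if non-`NULL`) seeds
#'   the run.
#' @param schedule An [annealing_schedule()], or `NULL` for constant
#'   temperature over `duration`.
#' @param duration Trajectory length in tau (ignored when a schedule is
#'   given; the schedule's `total_duration` governs).
#' @param record_stride Frame recording interval (tau).
#' @param velocities Optional N x 3 starting velocities; drawn from the
#'   Maxwell--Boltzmann distribution at the starting temperature when absent.
#' @return An object of class `cc_trajectory`: `frames` (N x 3 x F array),
#'   `times` (tau), `temperatures`, `final_velocities`, `sampling_start`
#'   (tau), and a `manifest` of seeds and settings.
#' @export
run_trajectory <- function(initial, stage, settings,
                           schedule = NULL, duration = NULL,
                           record_stride = 1, velocities = NULL) {
  check_configuration(initial)
  stopifnot(inherits(stage, "stage_potential"),
            inherits(settings, "langevin_settings"))
  if (nrow(initial) != stage$params$n_beads)
    stop("initial configuration does not match the stage's chain length")
  dt <- settings$timestep
  if (!is.null(schedule)) {
    total <- schedule$total_duration
    T0 <- schedule$T_start; T1 <- schedule$T_end
    ramp_steps <- as.integer(round(schedule$ramp_duration / dt))
    sampling_start <- total / 2
  } else {
    if (is.null(duration)) stop("either a schedule or a duration is required")
    total <- duration
    T0 <- T1 <- settings$temperature
    ramp_steps <- 0L
    sampling_start <- 0
  }
  n_steps <- as.integer(round(total / dt))
  record_every <- max(1L, as.integer(round(record_stride / dt)))
  if (!is.null(settings$seed)) set.seed(settings$seed)
  if (is.null(velocities)) velocities <- mb_velocities(nrow(initial), T0)
  out <- .cc_run_langevin(initial, velocities, unclass(stage$params),
                          unclass(stage$bias), max(abs(stage$bias)) > 0,
                          dt, settings$friction, T0, T1, ramp_steps,
                          n_steps, record_every)
  structure(list(frames = out$frames, times = as.numeric(out$times),
                 temperatures = as.numeric(out$temperatures),
                 final_velocities = out$final_velocities,
                 sampling_start = sampling_start,
                 manifest = list(seed = settings$seed,
                                 settings = unclass(settings),
                                 schedule = if (!is.null(schedule))
                                   unclass(schedule),
                                 stage = stage$label)),
            class = "cc_trajectory")
}

#' @export
print.cc_trajectory <- function(x, ...) {
  cat(sprintf("<cc_trajectory> %d beads, %d frames over %.3g tau (stage '%s')\n",
              dim(x$frames)[1], dim(x$frames)[3], max(x$times),
              x$manifest$stage))
  invisible(x)
}

#' Frames in the sampling window of a trajectory
#'
#' @param traj A `cc_trajectory`.
#' @return N x 3 x F array of frames with `time >= sampling_start`.
#' @export
sampling_frames <- function(traj) {
  keep <- traj$times >= traj$sampling_start - 1e-9
  traj$frames[, , keep, drop = FALSE]
}

#' Run independent replica trajectories
#'
#' Replica seeds are derived deterministically from `base_seed`, so a rerun
#' with the same base seed reproduces every trajectory bit-for-bit and
#' results do not depend on execution order.
#'
#' @param initials A single N x 3 matrix (recycled) or a list of starting
#'   configurations; replicas cycle through the list.
#' @param stage A [stage_potential()].
#' @param settings A [langevin_settings()] (its `seed` field is ignored).
#' @param schedule Optional [annealing_schedule()].
#' @param n_replicas Number of trajectories.
#' @param base_seed Integer base seed for the derived replica seeds.
#' @param ... Passed to [run_trajectory()] (`duration`, `record_stride`).
#' @return List of `cc_trajectory` objects with a `seeds` attribute.
#' @export
run_replicas <- function(initials, stage, settings, schedule = NULL,
                         n_replicas = 8, base_seed = 1, ...) {
  stopifnot(n_replicas >= 1)
  if (is.matrix(initials)) initials <- list(initials)
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_replicas)
  trajs <- vector("list", n_replicas)
  for (k in seq_len(n_replicas)) {
    s <- settings
    s$seed <- seeds[k]
    init <- initials[[(k - 1) %% length(initials) + 1]]
    trajs[[k]] <- tryCatch(
      run_trajectory(init, stage, s, schedule = schedule, ...),
      error = function(e)
        stop(sprintf("replica %d (seed %d) failed: %s",
                     k, seeds[k], conditionMessage(e)), call. = FALSE))
  }
  attr(trajs, "seeds") <- seeds
  trajs
}

#' Pool sampling-window frames of a replica set into an ensemble
#'
#' @param trajs List of `cc_trajectory` (from [run_replicas()]).
#' @param window Use only each trajectory's sampling window (default TRUE).
#' @return N x 3 x M array of structures.
#' @export
pool_ensemble <- function(trajs, window = TRUE) {
  grab <- if (window) sampling_frames else function(t) t$frames
  parts <- lapply(trajs, grab)
  n <- dim(parts[[1]])[1]
  total <- sum(vapply(parts, function(p) dim(p)[3], integer(1)))
  out <- array(0, c(n, 3, total))
  at <- 0
  for (p in parts) {
    m <- dim(p)[3]
    out[, , at + seq_len(m)] <- p
    at <- at + m
  }
  out
}

#' Export trajectory frames as xyz-style text
#'
#' Minimal multi-frame xyz for external viewers: per frame, a bead count
#' line, a comment line with the time, and `C x y z` rows.
#'
#' @param traj A `cc_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  n <- dim(traj$frames)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(traj$times)) {
    writeLines(c(as.character(n), sprintf("t = %g tau", traj$times[k]),
                 sprintf("C %.6f %.6f %.6f", traj$frames[, 1, k],
                         traj$frames[, 2, k], traj$frames[, 3, k])), con)
  }
  invisible(path)
}
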