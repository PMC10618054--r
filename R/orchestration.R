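#' Pipeline run configuration
#'
#' Two scale presets: `"desk"` (60 beads, 8 replicas, shortened annealed
#' trajectories, 10 calibration iterations) runs end-to-end on one CPU in
#' minutes and is the tested surface; `"paper"` restores the production
#' protocol (510 beads, 100 replicas, 1000 tau trajectories with a 250 tau
#' anneal) and is documented as cluster-scale. Every parameter can be
#' overridden.
#'
#' @param preset `"desk"` (default) or `"paper"`.
#' @param base_seed Seed from which all run seeds derive.
#' @param out_dir Optional output directory for artifacts and the manifest;
#'   `NULL` keeps everything in memory.
#' @param ... Overrides for any config field.
#' @return A list of class `run_config`.
#' @export
run_config <- function(preset = c("desk", "paper"), base_seed = 1,
                       out_dir = NULL, ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "desk") {
    list(n_loci = 60L, n_replicas = 8L, max_iter = 10L,
         ramp_duration = 15, total_duration = 60,
         switch_duration = 100, checkpoints = c(1, 10, 100),
         record_stride = 0.5, tol = 0.02, learning_rate = 2,
         alpha_max = 10, cluster_threshold = 0.8,
         min_population = 0.002, per_cluster = 2,
         insulation_window_kb = 500, coarse_resolution_kb = 1000)
  } else {
    list(n_loci = 510L, n_replicas = 100L, max_iter = 20L,
         ramp_duration = 250, total_duration = 1000,
         switch_duration = 1000, checkpoints = c(1, 10, 100, 1000),
         record_stride = 1, tol = 0.02, learning_rate = 2,
         alpha_max = 10, cluster_threshold = 0.8,
         min_population = 0.002, per_cluster = 2,
         insulation_window_kb = 500, coarse_resolution_kb = 1000)
  }
  cfg <- modifyList(cfg, list(...))
  cfg$preset <- preset
  cfg$base_seed <- as.integer(base_seed)
  cfg$out_dir <- out_dir
  structure(cfg, class = "run_config")
}

write_manifest <- function(cfg, name, extra = list()) {
  if (is.null(cfg$out_dir)) return(invisible(NULL))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  payload <- c(list(pipeline = name, timestamp = format(Sys.time()),
                    package_version = as.character(
                      utils::packageVersion("chromocycle"))),
               unclass(cfg)[setdiff(names(unclass(cfg)), "out_dir")], extra)
  jsonlite::write_json(payload, file.path(cfg$out_dir,
                                          paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

#' Calibrate one stage and compute its structural observables
#'
#' The single-stage workflow: calibrate the bias field against the target
#' map, pool the final equilibrium ensemble, and derive the full analysis
#' set -- geometry records, the free-energy landscape over (Rg, Delta), the
#' aligned-fluctuation matrix, the insulation profile with TAD boundaries,
#' and the enhanced-contact map with the compartment profile. When the
#' config has an `out_dir`, the stage archive, simulated map and a manifest
#' are written there.
#'
#' @param target Normalized target [contact_map()] (e.g. from
#'   [make_interphase_map()]).
#' @param config A [run_config()].
#' @param label Stage label for the calibrated potential.
#' @return A list of class `stage_result`: `calibration`, `stage`,
#'   `ensemble`, `geometry`, `landscape`, `fluctuation`, `insulation`,
#'   `boundaries`, `enhanced`, `compartments`.
#' @export
run_stage_pipeline <- function(target, config = run_config(),
                               label = "stage") {
  stopifnot(inherits(target, "contact_map"), inherits(config, "run_config"))
  n <- nrow(target$P)
  params <- homopolymer_params(n)
  cal <- calibrate(target, params,
                   settings = langevin_settings(),
                   schedule = annealing_schedule(
                     ramp_duration = config$ramp_duration,
                     total_duration = config$total_duration),
                   n_replicas = config$n_replicas,
                   max_iter = config$max_iter, tol = config$tol,
                   learning_rate = config$learning_rate,
                   alpha_max = config$alpha_max,
                   record_stride = config$record_stride,
                   base_seed = config$base_seed)
  cal$stage$label <- label
  geo <- geometry_records(cal$ensemble)
  fel <- free_energy_landscape(geo)
  # fluctuation analysis on a thinned ensemble keeps alignment tractable
  m <- dim(cal$ensemble)[3]
  pick <- unique(round(seq(1, m, length.out = min(m, 200))))
  aligned <- align_ensemble(cal$ensemble[, , pick, drop = FALSE])
  M <- fluctuation_matrix(aligned)
  insul <- insulation_profile(cal$P_sim, config$insulation_window_kb)
  bounds <- tad_boundaries(insul)
  emap <- enhanced_contacts(cal$P_sim, config$coarse_resolution_kb)
  comp <- tryCatch(compartment_profile(emap), error = function(e) NULL)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stage_potential(cal$stage,
                          file.path(config$out_dir,
                                    paste0(label, "_stage.txt")))
    write_contact_map(cal$P_sim,
                      file.path(config$out_dir, paste0(label, "_Psim.txt")))
    write.table(geo, file.path(config$out_dir, paste0(label, "_geometry.tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write_manifest(config, paste0(label, "_stage"),
                   list(mae = cal$mae, pearson = cal$pearson))
  }
  structure(list(calibration = cal, stage = cal$stage,
                 ensemble = cal$ensemble, geometry = geo, landscape = fel,
                 fluctuation = M, insulation = insul, boundaries = bounds,
                 enhanced = emap, compartments = comp),
            class = "stage_result")
}

#' Run a landscape-switching transition between two calibrated stages
#'
#' Clusters the source-stage ensemble, selects initial structures from the
#' qualifying clusters (population > `min_population`, `per_cluster` each),
#' switches the potential to the target stage, and relaxes. Checkpoint
#' ensembles yield Delta-M fluctuation differences, (Rg, Delta) series, and
#' the PCA pathway projection of the insulation-profile evolution against
#' the linear-interpolation baseline.
#'
#' @param source_result,target_result `stage_result`s from
#'   [run_stage_pipeline()].
#' @param config A [run_config()].
#' @return A list of class `transition_result`: `run` (the
#'   `switching_run`), `checkpoint_maps`, `checkpoint_mae` (to target),
#'   `delta_M` (per checkpoint), `geometry_series`, `pathway` (projection,
#'   baseline and `deviation`).
#' @export
run_transition_pipeline <- function(source_result, target_result,
                                    config = run_config()) {
  stopifnot(inherits(source_result, "stage_result"),
            inherits(target_result, "stage_result"))
  params <- source_result$stage$params
  target_map <- target_result$calibration$P_sim
  clusters <- cluster_ensemble(thin_ensemble(source_result$ensemble, 150),
                               config$cluster_threshold)
  initials <- select_initials(thin_ensemble(source_result$ensemble, 150),
                              clusters, config$min_population,
                              config$per_cluster)
  run <- switch_and_relax(initials, source_result$stage,
                          target_result$stage,
                          settings = langevin_settings(),
                          duration = config$switch_duration,
                          checkpoints = config$checkpoints,
                          record_stride = config$record_stride,
                          base_seed = config$base_seed + 13L)
  ts <- c(0, run$checkpoints)
  ensembles <- lapply(ts, function(t) time_resolved_ensemble(run, t))
  maps <- lapply(ensembles, estimate_contact_probabilities, params = params,
                 region = target_map$region)
  mae <- vapply(maps, function(m) map_error(m, target_map)[["mae"]],
                numeric(1))
  aligned0 <- align_ensemble(ensembles[[1]])
  M0 <- fluctuation_matrix(aligned0)
  dM <- lapply(seq_along(ts)[-1], function(k) {
    delta_M(fluctuation_matrix(align_ensemble(ensembles[[k]])), M0)
  })
  names(dM) <- paste0("t", run$checkpoints)
  geo <- do.call(rbind, lapply(seq_along(ts), function(k) {
    g <- geometry_records(ensembles[[k]])
    g$time <- ts[k]
    g
  }))
  # pathway PCA: mean insulation profile at each checkpoint vs the linear
  # baseline between the two stage maps
  profs <- do.call(rbind, lapply(maps, function(m)
    insulation_profile(m, config$insulation_window_kb)$scores))
  baseline <- linear_interpolation_path(source_result$calibration$P_sim,
                                        target_map, n_steps = 11,
                                        observable = "insulation",
                                        window_kb =
                                          config$insulation_window_kb)
  model <- fit_profile_pca(rbind(profs, baseline$profiles))
  sim_path <- project_series(model, profs, times = ts)
  base_path <- project_series(model, baseline$profiles, times = baseline$s)
  deviation <- tryCatch(path_deviation(sim_path, base_path),
                        error = function(e) NA_real_)
  res <- structure(list(run = run, checkpoint_times = ts,
                        checkpoint_maps = maps, checkpoint_mae = mae,
                        delta_M = dM, geometry_series = geo,
                        pathway = list(model = model, simulated = sim_path,
                                       baseline = base_path,
                                       deviation = deviation)),
                   class = "transition_result")
  if (!is.null(config$out_dir)) {
    write.table(geo, file.path(config$out_dir, sprintf(
      "%s_to_%s_geometry.tsv", run$source_label, run$target_label)),
      sep = "\t", row.names = FALSE, quote = FALSE)
    write_manifest(config, sprintf("%s_to_%s_transition",
                                   run$source_label, run$target_label),
                   list(checkpoint_mae = mae, deviation = deviation))
  }
  res
}

thin_ensemble <- function(ens, max_size) {
  m <- dim(ens)[3]
  if (m <= max_size) return(ens)
  ens[, , unique(round(seq(1, m, length.out = max_size))), drop = FALSE]
}
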