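config_schema <- list(
  system = c("site_center", "well_depth", "well_width", "excluded_radius",
             "confinement_radius", "copy_repulsion_strength",
             "copy_repulsion_range", "wall_stiffness", "confinement_stiffness"),
  dynamics = c("dt", "temperature", "friction", "n_steps_per_frame",
               "frames_per_segment"),
  sampling = c("n_replicas", "cutoff", "max_cycles", "seed",
               "convergence_window", "convergence_tol",
               "aggregation_threshold", "aggregation_policy", "rank_scope"),
  rc = c("kind", "copy_reduction", "normalize", "selection", "selection_file",
         "reference", "components", "weights"),
  arrangement = c("n_copies", "r_min", "r_max", "min_separation"))

check_keys <- function(section, keys, allowed) {
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop(sprintf("unknown config key '%s.%s' (allowed: %s)", section,
                 unknown[1], paste(allowed, collapse = ", ")))
}

rc_from_list <- function(x, base_dir = ".") {
  if (is.null(x$kind)) stop("config key 'rc.kind' is required")
  sel <- NULL
  if (!is.null(x$selection))
    sel <- atom_selection(ligand = x$selection$ligand, site = x$selection$site)
  else if (!is.null(x$selection_file))
    sel <- read_selection_table(file.path(base_dir, x$selection_file))
  ref <- if (!is.null(x$reference))
    matrix(unlist(x$reference), ncol = 3, byrow = TRUE) else NULL
  comps <- if (!is.null(x$components))
    lapply(x$components, rc_from_list, base_dir = base_dir) else NULL
  rc_spec(kind = x$kind, selection = sel, reference = ref,
          components = comps, weights = x$weights,
          copy_reduction = x$copy_reduction %||% "min",
          normalize = x$normalize %||% "zscore")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate a run configuration
#'
#' Reads a YAML file with sections `system` (toy potential), `dynamics`
#' (integrator), `sampling` (cycle engine), `rc` (reaction coordinate) and
#' `arrangement` (initial ligand-copy placement). Missing values take the
#' documented defaults (10 replicas, 10 frames per segment); unknown keys are
#' rejected by name.
#'
#' @param path YAML file.
#' @return an object of class `pacs_config`: list with `system`, `dynamics`,
#'   `sampling` (a [sampling_config()] carrying the rc spec), `arrangement`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  check_keys("<top level>", names(raw), names(config_schema))
  for (sec in names(config_schema))
    if (!is.null(raw[[sec]]))
      check_keys(sec, names(raw[[sec]]), config_schema[[sec]])
  if (is.null(raw$rc)) stop("config key 'rc.kind' is required")
  sys <- do.call(toy_spec, raw$system %||% list())
  dyn <- do.call(dynamics_params, raw$dynamics %||% list())
  rc <- rc_from_list(raw$rc, base_dir = dirname(path))
  sam <- raw$sampling %||% list()
  sampling <- sampling_config(
    n_replicas = sam$n_replicas %||% 10L,
    frames_per_segment = dyn$frames_per_segment,
    cutoff = sam$cutoff %||% NA,
    max_cycles = sam$max_cycles %||% 50L,
    seed = sam$seed %||% 1L,
    rc = rc,
    convergence_window = sam$convergence_window %||% 5L,
    convergence_tol = sam$convergence_tol %||% 0.05,
    aggregation_threshold = sam$aggregation_threshold %||% 0.5,
    aggregation_policy = sam$aggregation_policy %||% "none",
    rank_scope = sam$rank_scope %||% "cycle")
  arr <- raw$arrangement %||% list()
  arrangement <- list(
    n_copies = arr$n_copies %||% 6L,
    r_min = arr$r_min %||% sys$excluded_radius,
    r_max = arr$r_max %||% sys$confinement_radius,
    min_separation = arr$min_separation %||% 0)
  structure(list(system = sys, dynamics = dyn, sampling = sampling,
                 arrangement = arrangement),
            class = "pacs_config")
}

rc_to_list <- function(rc) {
  out <- list(kind = rc$kind, copy_reduction = rc$copy_reduction,
              normalize = rc$normalize)
  if (!is.null(rc$selection))
    out$selection <- list(ligand = lapply(rc$selection$ligand, as.integer),
                          site = as.integer(rc$selection$site))
  if (!is.null(rc$reference))
    out$reference <- lapply(seq_len(nrow(rc$reference)),
                            function(i) as.numeric(rc$reference[i, ]))
  if (!is.null(rc$components)) {
    out$components <- lapply(rc$components, rc_to_list)
    out$weights <- rc$weights
  }
  out
}

#' Serialise a configuration to a plain list
#' @param x a `pacs_config` or [sampling_config()].
#' @return a nested list suitable for YAML/JSON output.
#' @export
serialize_config <- function(x) {
  if (inherits(x, "sampling_config")) {
    out <- unclass(x)
    out$rc <- if (is.null(x$rc)) NULL else rc_to_list(x$rc)
    return(out)
  }
  list(system = unclass(x$system),
       dynamics = unclass(x$dynamics),
       sampling = list(n_replicas = x$sampling$n_replicas,
                       cutoff = x$sampling$cutoff,
                       max_cycles = x$sampling$max_cycles,
                       seed = x$sampling$seed,
                       convergence_window = x$sampling$convergence_window,
                       convergence_tol = x$sampling$convergence_tol,
                       aggregation_threshold = x$sampling$aggregation_threshold,
                       aggregation_policy = x$sampling$aggregation_policy,
                       rank_scope = x$sampling$rank_scope),
       rc = rc_to_list(x$sampling$rc),
       arrangement = x$arrangement)
}

#' Write a configuration back to YAML
#'
#' Inverse of [load_config()] with all defaults materialised, so
#' load / dump / load round-trips to an identical configuration.
#'
#' @param config a `pacs_config`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  out <- serialize_config(config)
  out$sampling$cutoff <- if (is.na(out$sampling$cutoff)) NULL else out$sampling$cutoff
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full cascade protocol from a configuration
#'
#' Builds the toy system, arranges the ligand copies, runs the selection loop
#' and (optionally) writes the results directory.
#'
#' @param config a `pacs_config` (from [load_config()] or [make_fixture()])
#'   or the path to a YAML config.
#' @param out_dir optional results directory.
#' @param seed optional override of the configured seed.
#' @param stop_after optional checkpoint cycle (see [pacs_resume()]).
#' @return the [run_pacs()] result, invisibly when writing.
#' @export
pacs_run <- function(config, out_dir = NULL, seed = NULL, stop_after = Inf) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "pacs_config"))
  if (!is.null(seed)) config$sampling$seed <- as.integer(seed)
  run_seed <- config$sampling$seed
  arr <- config$arrangement
  initial <- arrange_ligand_copies(
    config$system, n_copies = arr$n_copies, r_min = arr$r_min,
    r_max = arr$r_max, min_separation = arr$min_separation,
    seed = derive_seed(run_seed, "arrange"),
    temperature = config$dynamics$temperature)
  engine <- toy_engine_adapter(config$system, config$dynamics,
                               arrange_shell = c(arr$r_min, arr$r_max),
                               min_separation = arr$min_separation)
  result <- run_pacs(config$sampling, engine, initial,
                     stop_after = stop_after)
  result$pacs_config <- config
  if (!is.null(out_dir)) {
    write_run(result, out_dir)
    dump_config(config, file.path(out_dir, "config.yaml"))
    return(invisible(result))
  }
  result
}

#' Resume a checkpointed run from its results directory
#'
#' Reconstructs the completed cycles from `cycles.csv` and the per-cycle XYZ
#' archives (written at full precision), then continues the loop to
#' termination. Because every random stream is derived from the run seed and
#' the cycle/replica indices, the resumed run is identical to an
#' uninterrupted one.
#'
#' @param out_dir results directory written by [pacs_run()].
#' @return the completed [run_pacs()] result, invisibly.
#' @export
pacs_resume <- function(out_dir) {
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  config <- load_config(file.path(out_dir, "config.yaml"))
  if (manifest$termination_reason != "checkpoint") {
    message("run already terminated (", manifest$termination_reason, ")")
    # nothing to do; re-load not supported beyond the manifest echo
  }
  run_seed <- config$sampling$seed
  arr <- config$arrangement
  initial <- arrange_ligand_copies(
    config$system, n_copies = arr$n_copies, r_min = arr$r_min,
    r_max = arr$r_max, min_separation = arr$min_separation,
    seed = derive_seed(run_seed, "arrange"),
    temperature = config$dynamics$temperature)
  engine <- toy_engine_adapter(config$system, config$dynamics,
                               arrange_shell = c(arr$r_min, arr$r_max),
                               min_separation = arr$min_separation)
  done <- as.integer(manifest$cycles_completed)
  N <- config$sampling$n_replicas
  M <- config$sampling$frames_per_segment
  # verify archive integrity, then rebuild run state
  for (cyc in seq_len(done)) {
    f <- sprintf("traj_cycle%04d.xyz", cyc)
    want <- manifest$checksums[[f]]
    have <- unname(tools::md5sum(file.path(out_dir, f)))
    if (!identical(want, have))
      stop("archive checksum mismatch for ", f, "; cannot resume")
  }
  archive <- lapply(seq_len(done), function(cyc)
    read_xyz(file.path(out_dir, sprintf("traj_cycle%04d.xyz", cyc))))
  cycles <- list(); parents <- list(); pool_tab <- list()
  best_so_far <- Inf
  for (cyc in seq_len(done)) {
    pool <- archive[[cyc]]
    rc_vals <- evaluate_rc_pool(pool, config$sampling$rc)
    prov <- data.frame(cycle = cyc, replica = rep(seq_len(N), each = M),
                       frame = rep(seq_len(M), N), rc = rc_vals)
    prov$id <- snap_id(prov$cycle, prov$replica, prov$frame)
    sel_ids <- rank_and_select(prov, N)
    best_so_far <- min(best_so_far, min(rc_vals))
    cycles[[cyc]] <- list(cycle_index = cyc, rc_values = rc_vals,
                          provenance = prov, selected = sel_ids,
                          best_rc_this_cycle = min(rc_vals),
                          best_rc_so_far = best_so_far)
    parents[[cyc]] <- sel_ids
    prov$selected <- prov$id %in% sel_ids
    pool_tab[[cyc]] <- prov
  }
  last_pool <- archive[[done]]
  lookup <- stats::setNames(seq_along(last_pool), pool_tab[[done]]$id)
  seeds <- lapply(cycles[[done]]$selected, function(id) last_pool[[lookup[[id]]]])
  result <- run_pacs(config$sampling, engine, initial,
                     .resume = list(cycles = cycles, parents = parents,
                                    archive = archive, pool_tab = pool_tab,
                                    seeds = seeds))
  result$pacs_config <- config
  write_run(result, out_dir)
  invisible(result)
}
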