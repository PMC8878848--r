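#' Sampling configuration for the cascade-selection engine
#'
#' @param n_replicas number of short segments per cycle (N).
#' @param frames_per_segment snapshots recorded per segment (M).
#' @param cutoff terminate once the best reaction-coordinate value in a cycle
#'   falls below this threshold; `NA` disables the cutoff test.
#' @param max_cycles hard cycle limit.
#' @param seed run-level seed; every random stream is derived from it.
#' @param rc an [rc_spec()] used to rank snapshots.
#' @param convergence_window cycles per window for the distribution-based
#'   convergence test (0 disables it).
#' @param convergence_tol L1 threshold between consecutive window-averaged
#'   RC histograms.
#' @param aggregation_threshold copy-copy COM distance below which copies
#'   count as aggregated.
#' @param aggregation_policy `"none"` or `"reset"` (re-randomise aggregated
#'   copies in selected seeds, keeping the best copy).
#' @param rank_scope `"cycle"` ranks only the most recent cycle's pool (the
#'   default); `"global"` ranks every snapshot generated so far.
#' @return an object of class `sampling_config`.
#' @export
sampling_config <- function(n_replicas = 10, frames_per_segment = 10,
                            cutoff = NA, max_cycles = 50, seed = 1,
                            rc = NULL, convergence_window = 5,
                            convergence_tol = 0.05,
                            aggregation_threshold = 0.5,
                            aggregation_policy = c("none", "reset"),
                            rank_scope = c("cycle", "global")) {
  if (n_replicas < 1 || frames_per_segment < 1 || max_cycles < 1)
    stop("n_replicas, frames_per_segment and max_cycles must all be >= 1")
  if (!is.na(cutoff) && cutoff <= 0) stop("cutoff must be > 0 (or NA to disable)")
  structure(list(n_replicas = as.integer(n_replicas),
                 frames_per_segment = as.integer(frames_per_segment),
                 cutoff = cutoff, max_cycles = as.integer(max_cycles),
                 seed = as.integer(seed), rc = rc,
                 convergence_window = as.integer(convergence_window),
                 convergence_tol = convergence_tol,
                 aggregation_threshold = aggregation_threshold,
                 aggregation_policy = match.arg(aggregation_policy),
                 rank_scope = match.arg(rank_scope)),
            class = "sampling_config")
}

snap_id <- function(cycle, replica, frame) {
  sprintf("c%04d.r%03d.f%03d", cycle, replica, frame)
}

#' Rank a snapshot pool and select reseeding candidates
#'
#' Orders the pool ascending in the reaction coordinate and returns the ids of
#' the `n_select` best snapshots. Ties are broken deterministically by lower
#' replica then lower frame index (and lower cycle, if the pool spans cycles).
#' If the pool holds fewer snapshots than `n_select`, ids are recycled
#' round-robin in rank order so exactly `n_select` seeds come back.
#'
#' @param pool data frame with columns `id`, `rc` and (for tie-breaking)
#'   `cycle`, `replica`, `frame`; missing provenance columns default to row
#'   order.
#' @param n_select number of seeds to return.
#' @return character vector of `n_select` ids, best first.
#' @export
rank_and_select <- function(pool, n_select) {
  if (is.null(pool) || nrow(pool) == 0) stop("cannot select from an empty pool")
  if (n_select < 1) stop("n_select must be >= 1")
  cyc <- if ("cycle" %in% names(pool)) pool$cycle else rep(0L, nrow(pool))
  rep_ <- if ("replica" %in% names(pool)) pool$replica else seq_len(nrow(pool))
  frm <- if ("frame" %in% names(pool)) pool$frame else seq_len(nrow(pool))
  ord <- order(pool$rc, cyc, rep_, frm)
  ids <- pool$id[ord]
  ids[(seq_len(n_select) - 1L) %% length(ids) + 1L]
}

#' Single-linkage aggregation detection among ligand copies
#'
#' Clusters ligand copies whose COM-to-COM distance is below `threshold`
#' (single linkage, so chains of close copies merge). Aggregation is flagged
#' when any cluster holds two or more copies.
#'
#' @param snap a snapshot with at least two ligand copies.
#' @param threshold length below which two copies count as close.
#' @param selection optional [atom_selection()]; defaults to the copy labels
#'   in the state.
#' @return list of integer vectors (copy indices per cluster), with attribute
#'   `aggregated` (logical).
#' @export
detect_aggregation <- function(snap, threshold, selection = NULL) {
  state <- snap$state
  if (is.null(selection)) selection <- selection_from_state(state)
  ncop <- length(selection$ligand)
  if (ncop < 2) stop("aggregation detection requires >= 2 ligand copies")
  coms <- t(vapply(selection$ligand, function(ix) {
    center_of_mass(state$positions[ix, , drop = FALSE])
  }, numeric(3)))
  hc <- stats::hclust(stats::dist(coms), method = "single")
  grp <- stats::cutree(hc, h = threshold - .Machine$double.eps)
  clusters <- split(seq_len(ncop), grp)
  names(clusters) <- NULL
  structure(clusters, aggregated = any(lengths(clusters) >= 2))
}

rc_histogram <- function(values, breaks) {
  h <- graphics::hist(pmin(pmax(values, breaks[1]), breaks[length(breaks)]),
                      breaks = breaks, plot = FALSE)
  h$counts / sum(h$counts)
}

#' Termination test for the cascade loop
#'
#' Checks, in order: (1) cutoff — the best RC value of the latest cycle fell
#' below `config$cutoff`; (2) convergence — the L1 distance between the
#' RC-value histograms averaged over the last `convergence_window` cycles and
#' over the preceding window fell below `convergence_tol` (fixed bins spanning
#' 0 to the first cycle's maximum RC); (3) the cycle limit.
#'
#' @param history list of cycle records (each with `rc_values` and
#'   `best_rc_this_cycle`).
#' @param config a [sampling_config()].
#' @return one of `"continue"`, `"cutoff"`, `"converged"`, `"max_cycles"`.
#' @export
check_termination <- function(history, config) {
  if (length(history) == 0) stop("history must contain at least one cycle")
  last <- history[[length(history)]]
  if (!is.na(config$cutoff) && last$best_rc_this_cycle < config$cutoff)
    return("cutoff")
  w <- config$convergence_window
  if (w > 0 && length(history) >= 2 * w) {
    hi <- max(history[[1]]$rc_values)
    breaks <- seq(0, max(hi, 1e-12), length.out = 21L)
    n <- length(history)
    recent <- rowMeans(vapply(history[(n - w + 1):n],
                              function(h) rc_histogram(h$rc_values, breaks),
                              numeric(20L)))
    prev <- rowMeans(vapply(history[(n - 2 * w + 1):(n - w)],
                            function(h) rc_histogram(h$rc_values, breaks),
                            numeric(20L)))
    if (sum(abs(recent - prev)) < config$convergence_tol) return("converged")
  }
  if (length(history) >= config$max_cycles) return("max_cycles")
  "continue"
}

#' Dynamics adapter for the built-in toy engine
#'
#' Wraps the reduced Langevin substrate in the backend contract the cascade
#' loop drives: `propagate(snapshot, seed, cycle, replica)` returning exactly
#' M snapshots, `regenerate_velocities(snapshot, seed)` drawing fresh
#' Maxwell-Boltzmann velocities, and an optional `rearrange` used by the
#' aggregation-reset policy.
#'
#' @param spec a [toy_spec()].
#' @param params a [dynamics_params()].
#' @param arrange_shell radii `c(r_min, r_max)` used when re-randomising
#'   aggregated copies.
#' @param min_separation pairwise separation enforced when re-randomising.
#' @return an object of class `engine_adapter`.
#' @export
toy_engine_adapter <- function(spec, params, arrange_shell = NULL,
                               min_separation = 0) {
  if (is.null(arrange_shell))
    arrange_shell <- c(max(spec$excluded_radius, 1e-6), spec$confinement_radius)
  structure(list(
    frames_per_segment = params$frames_per_segment,
    spec = spec, params = params,
    propagate = function(snap, seed, cycle, replica) {
      run_segment(snap$state, spec, params, seed, cycle = cycle,
                  replica = replica)
    },
    regenerate_velocities = function(snap, seed) {
      st <- snap$state
      vel <- draw_mb_velocities(st$masses, params$temperature, seed)
      vel[st$copy_id == 0L, ] <- 0
      snapshot(system_state(st$positions, vel, st$masses, st$copy_id),
               cycle = snap$cycle, replica = snap$replica, frame = snap$frame)
    },
    rearrange = function(snap, keep_copies, seed) {
      st <- snap$state
      sel <- selection_from_state(st)
      redo <- setdiff(seq_along(sel$ligand), keep_copies)
      set.seed(seed)
      pos <- st$positions
      kept <- lapply(keep_copies, function(k) pos[sel$ligand[[k]], , drop = FALSE])
      kept_pts <- do.call(rbind, kept)
      for (k in redo) {
        for (attempt in seq_len(5000L)) {
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          r <- (arrange_shell[1]^3 + stats::runif(1) *
                  (arrange_shell[2]^3 - arrange_shell[1]^3))^(1 / 3)
          x <- spec$site_center + r * u
          dmin <- if (is.null(kept_pts) || nrow(kept_pts) == 0) Inf else
            min(sqrt(rowSums(sweep(kept_pts, 2, x)^2)))
          if (dmin >= min_separation) break
          if (attempt == 5000L)
            stop("packing failure during aggregation reset: min_separation unsatisfiable")
        }
        pos[sel$ligand[[k]], ] <- matrix(x, length(sel$ligand[[k]]), 3, byrow = TRUE)
        kept_pts <- rbind(kept_pts, x)
      }
      snapshot(system_state(pos, st$velocities, st$masses, st$copy_id),
               cycle = snap$cycle, replica = snap$replica, frame = snap$frame)
    }),
    class = "engine_adapter")
}

#' Run the adaptive cascade-selection loop
#'
#' Cycle 1 seeds all N replicas from `initial` with freshly drawn velocities.
#' Each later cycle ranks the previous cycle's N x M snapshot pool by the
#' configured reaction coordinate, selects the top N, regenerates velocities,
#' and propagates a new short segment from each seed. The loop stops per
#' [check_termination()]. Runs are fully reproducible from `config$seed`.
#'
#' @param config a [sampling_config()] (must carry an `rc` spec).
#' @param engine an engine adapter, e.g. [toy_engine_adapter()].
#' @param initial starting [system_state()] (the reactant).
#' @param keep_snapshots store every snapshot in the result (needed for XYZ
#'   export and for re-projection onto other coordinates).
#' @param stop_after checkpoint after this many cycles (the run can be
#'   continued later with identical results; see [pacs_resume()]).
#' @param .resume internal: partial run state to continue from.
#' @return an object of class `pacs_result`: cycle records, the full
#'   (cycle, replica, frame, rc, selected) table, parent links, termination
#'   reason, and the snapshot archive.
#' @export
run_pacs <- function(config, engine, initial, keep_snapshots = TRUE,
                     stop_after = Inf, .resume = NULL) {
  stopifnot(inherits(config, "sampling_config"))
  if (is.null(config$rc)) stop("config$rc must be an rc_spec")
  N <- config$n_replicas
  M <- config$frames_per_segment
  seeds <- replicate(N, snapshot(initial, cycle = 0L, replica = 0L, frame = 0L),
                     simplify = FALSE)
  cycles <- list()
  parents <- list()
  archive <- list()
  pool_tab <- list()
  best_so_far <- Inf
  reason <- "max_cycles"
  first_cycle <- 1L
  if (!is.null(.resume)) {
    cycles <- .resume$cycles
    parents <- .resume$parents
    archive <- .resume$archive
    pool_tab <- .resume$pool_tab
    seeds <- .resume$seeds
    best_so_far <- cycles[[length(cycles)]]$best_rc_so_far
    first_cycle <- length(cycles) + 1L
    status <- check_termination(cycles, config)
    if (status != "continue")
      return(structure(list(cycles = cycles,
                            table = do.call(rbind, pool_tab),
                            parents = parents,
                            termination_reason = status, config = config,
                            archive = if (keep_snapshots) archive else NULL),
                       class = "pacs_result"))
  }

  for (cyc in seq.int(first_cycle, length.out = max(0L, config$max_cycles - first_cycle + 1L))) {
    pool <- vector("list", N * M)
    for (r in seq_len(N)) {
      seed_snap <- seeds[[r]]
      if (config$aggregation_policy == "reset" &&
          length(unique(initial$copy_id[initial$copy_id > 0])) >= 2) {
        cl <- detect_aggregation(seed_snap, config$aggregation_threshold)
        if (attr(cl, "aggregated")) {
          pc <- evaluate_rc_copies(seed_snap, config$rc)
          seed_snap <- engine$rearrange(
            seed_snap, keep_copies = which.min(pc),
            seed = derive_seed(config$seed, "rearrange", cyc, r))
        }
      }
      seed_snap <- engine$regenerate_velocities(
        seed_snap, derive_seed(config$seed, "velocities", cyc, r))
      seg <- engine$propagate(seed_snap,
                              derive_seed(config$seed, "segment", cyc, r),
                              cycle = cyc, replica = r)
      if (length(seg) != M)
        stop(sprintf("engine returned %d frames (expected %d) at cycle %d replica %d",
                     length(seg), M, cyc, r))
      pool[((r - 1) * M + 1):(r * M)] <- seg
    }
    rc_vals <- evaluate_rc_pool(pool, config$rc)
    prov <- data.frame(
      cycle = cyc,
      replica = rep(seq_len(N), each = M),
      frame = rep(seq_len(M), N),
      rc = rc_vals,
      stringsAsFactors = FALSE)
    prov$id <- snap_id(prov$cycle, prov$replica, prov$frame)

    rank_pool <- if (config$rank_scope == "global" && length(pool_tab) > 0)
      rbind(do.call(rbind, lapply(pool_tab, function(p) p[names(prov)])), prov)
    else prov
    if (config$rc$copy_reduction == "per_copy") {
      # per-(snapshot, copy) ranking is defined on the current cycle's pool
      percopy <- lapply(seq_along(pool), function(i)
        evaluate_rc_copies(pool[[i]], config$rc))
      expanded <- prov[rep(seq_len(nrow(prov)),
                           lengths(percopy)), , drop = FALSE]
      expanded$rc <- unlist(percopy)
      sel_ids <- unique(rank_and_select(expanded, nrow(expanded)))
      sel_ids <- sel_ids[(seq_len(N) - 1L) %% length(sel_ids) + 1L]
    } else {
      sel_ids <- rank_and_select(rank_pool, N)
    }

    best_this <- min(rc_vals)
    best_so_far <- min(best_so_far, best_this)
    rec <- list(cycle_index = cyc, rc_values = rc_vals, provenance = prov,
                selected = sel_ids, best_rc_this_cycle = best_this,
                best_rc_so_far = best_so_far)
    cycles[[cyc]] <- rec
    parents[[cyc]] <- sel_ids
    prov$selected <- prov$id %in% sel_ids
    pool_tab[[cyc]] <- prov
    if (keep_snapshots) archive[[cyc]] <- pool

    status <- check_termination(cycles, config)
    if (status != "continue") { reason <- status; break }
    if (cyc >= stop_after) { reason <- "checkpoint"; break }

    lookup <- stats::setNames(seq_along(pool), prov$id)
    seeds <- lapply(sel_ids, function(id) {
      if (id %in% names(lookup)) pool[[lookup[[id]]]]
      else archive_lookup(archive, id, M)
    })
  }

  structure(list(cycles = cycles,
                 table = do.call(rbind, pool_tab),
                 parents = parents,
                 termination_reason = reason,
                 config = config,
                 archive = if (keep_snapshots) archive else NULL),
            class = "pacs_result")
}

archive_lookup <- function(archive, id, M) {
  m <- regmatches(id, regexec("^c(\\d+)\\.r(\\d+)\\.f(\\d+)$", id))[[1]]
  cyc <- as.integer(m[2]); r <- as.integer(m[3]); f <- as.integer(m[4])
  if (cyc > length(archive) || is.null(archive[[cyc]]))
    stop("broken parent link: snapshot ", id,
         " not in archive (re-run with keep_snapshots = TRUE for global ranking)")
  archive[[cyc]][[(r - 1L) * M + f]]
}

#' Back-trace binding pathways from a finished run
#'
#' For every snapshot of the final cycle whose reaction-coordinate value lies
#' below the cutoff, follows the parent links (which seed each segment was
#' restarted from) back to the reactant, yielding the chain of
#' (cycle, replica, frame) ancestors — one sampled binding pathway per
#' terminal snapshot.
#'
#' @param result a [run_pacs()] result.
#' @param cutoff RC threshold defining terminal snapshots; defaults to the
#'   run's configured cutoff.
#' @return list of data frames with columns `cycle`, `replica`, `frame`,
#'   `rc`, ordered from cycle 0 (the reactant, rc `NA`) to the terminal
#'   snapshot.
#' @export
trace_binding_paths <- function(result, cutoff = result$config$cutoff) {
  if (is.na(cutoff)) stop("no cutoff configured and none supplied")
  nlast <- length(result$cycles)
  last <- result$cycles[[nlast]]
  term <- last$provenance[last$provenance$rc < cutoff, , drop = FALSE]
  lapply(seq_len(nrow(term)), function(i) {
    chain <- term[i, c("cycle", "replica", "frame", "rc")]
    cyc <- term$cycle[i]; rep_ <- term$replica[i]
    while (cyc > 1) {
      pid <- result$parents[[cyc - 1]][rep_]
      if (is.na(pid) || is.null(pid))
        stop("broken parent link at cycle ", cyc, " replica ", rep_)
      m <- regmatches(pid, regexec("^c(\\d+)\\.r(\\d+)\\.f(\\d+)$", pid))[[1]]
      cyc <- as.integer(m[2]); rep_ <- as.integer(m[3]); f <- as.integer(m[4])
      prov <- result$cycles[[cyc]]$provenance
      row <- prov[prov$replica == rep_ & prov$frame == f, c("cycle", "replica", "frame", "rc")]
      chain <- rbind(row, chain)
    }
    chain <- rbind(data.frame(cycle = 0L, replica = 0L, frame = 0L, rc = NA_real_),
                   chain)
    rownames(chain) <- NULL
    chain
  })
}

#' Plain (non-adaptive) baseline runs with the same step budget
#'
#' Runs `n_replicas` independent continuous Langevin trajectories from the
#' same reactant, each `max_cycles` segments long, so the total number of
#' integration steps equals one cascade run. Used to measure the enrichment
#' the selection rule provides over brute-force dynamics.
#'
#' @param config a [sampling_config()].
#' @param engine an engine adapter.
#' @param initial starting [system_state()].
#' @return list with `min_rc` (best RC seen across all replicas), `reached`
#'   (logical, cutoff reached), and `rc_trace` (per-replica RC minima per
#'   segment).
#' @export
run_plain_baseline <- function(config, engine, initial) {
  N <- config$n_replicas
  best <- Inf
  rc_trace <- matrix(NA_real_, config$max_cycles, N)
  for (r in seq_len(N)) {
    snap <- snapshot(initial, 0L, r, 0L)
    snap <- engine$regenerate_velocities(
      snap, derive_seed(config$seed, "plain-velocities", 0L, r))
    for (cyc in seq_len(config$max_cycles)) {
      seg <- engine$propagate(snap, derive_seed(config$seed, "plain", cyc, r),
                              cycle = cyc, replica = r)
      vals <- evaluate_rc_pool(seg, config$rc)
      rc_trace[cyc, r] <- min(vals)
      best <- min(best, vals)
      snap <- seg[[length(seg)]]
      if (!is.na(config$cutoff) && best < config$cutoff) break
    }
    if (!is.na(config$cutoff) && best < config$cutoff) break
  }
  list(min_rc = best,
       reached = !is.na(config$cutoff) && best < config$cutoff,
       rc_trace = rc_trace)
}
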