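#' @useDynLib pacsmd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Toy binding-site potential specification
#'
#' Defines the reduced-unit substrate on which the cascade-selection protocol
#' runs: a frozen binding site at `site_center` carrying an attractive Gaussian
#' funnel well, a soft-core excluded sphere standing in for the protein body,
#' a harmonic spherical wall confining the ligand copies, and a compact-support
#' pairwise repulsion between distinct copies that keeps a multi-copy ligand
#' environment from aggregating. Energies are in units of kBT = 1 and lengths
#' in a reduced, roughly angstrom-like unit.
#'
#' @param site_center numeric 3-vector, position of the binding site.
#' @param well_depth depth of the Gaussian funnel well (>= 0).
#' @param well_width standard-deviation width of the well (> 0).
#' @param excluded_radius radius of the soft protein core around the site;
#'   0 disables the core.
#' @param confinement_radius radius beyond which the harmonic outer wall acts.
#' @param copy_repulsion_strength energy scale of the inter-copy repulsion.
#' @param copy_repulsion_range distance at which the inter-copy repulsion
#'   reaches zero (compact support).
#' @param wall_stiffness spring constant of the soft core wall.
#' @param confinement_stiffness spring constant of the outer confinement.
#' @return an object of class `toy_spec`.
#' @export
toy_spec <- function(site_center = c(0, 0, 0), well_depth = 5, well_width = 1,
                     excluded_radius = 1, confinement_radius = 8,
                     copy_repulsion_strength = 2, copy_repulsion_range = 1,
                     wall_stiffness = 50, confinement_stiffness = 5) {
  stopifnot(length(site_center) == 3, is.finite(site_center))
  if (!(well_width > 0)) stop("well_width must be > 0")
  if (excluded_radius > 0 && !(excluded_radius < confinement_radius))
    stop("excluded_radius must be smaller than confinement_radius")
  en <- c(well_depth, copy_repulsion_strength, wall_stiffness,
          confinement_stiffness)
  if (any(en < 0)) stop("all energy scales must be >= 0")
  structure(list(site_center = as.numeric(site_center),
                 well_depth = well_depth, well_width = well_width,
                 excluded_radius = excluded_radius,
                 confinement_radius = confinement_radius,
                 copy_repulsion_strength = copy_repulsion_strength,
                 copy_repulsion_range = copy_repulsion_range,
                 wall_stiffness = wall_stiffness,
                 confinement_stiffness = confinement_stiffness),
            class = "toy_spec")
}

#' Instantaneous system state
#'
#' Positions, velocities, masses and copy labels of all particles at one
#' instant. `copy_id == 0` marks the frozen site marker; labels >= 1 assign a
#' particle to one mobile ligand copy.
#'
#' @param positions n x 3 numeric matrix.
#' @param velocities n x 3 numeric matrix.
#' @param masses positive numeric vector of length n.
#' @param copy_id integer vector of length n (0 = site marker).
#' @return an object of class `system_state`.
#' @export
system_state <- function(positions, velocities, masses, copy_id) {
  positions <- as.matrix(positions)
  velocities <- as.matrix(velocities)
  n <- nrow(positions)
  if (ncol(positions) != 3 || !identical(dim(velocities), dim(positions)))
    stop("positions and velocities must be matching n x 3 matrices")
  if (length(masses) != n || length(copy_id) != n)
    stop("masses and copy_id must have one entry per particle")
  if (any(masses <= 0)) stop("masses must be > 0")
  structure(list(positions = positions, velocities = velocities,
                 masses = as.numeric(masses),
                 copy_id = as.integer(copy_id)),
            class = "system_state")
}

#' Stochastic-dynamics parameters
#'
#' @param dt integration time step (> 0).
#' @param temperature kBT in reduced units (>= 0).
#' @param friction Langevin friction, inverse time (> 0).
#' @param n_steps_per_frame integration steps between recorded frames.
#' @param frames_per_segment frames recorded per short segment (the
#'   per-segment snapshot count M).
#' @return an object of class `dynamics_params`.
#' @export
dynamics_params <- function(dt = 0.02, temperature = 1, friction = 10,
                            n_steps_per_frame = 5, frames_per_segment = 10) {
  if (!(dt > 0)) stop("dt must be > 0")
  if (temperature < 0) stop("temperature must be >= 0")
  if (!(friction > 0)) stop("friction must be > 0")
  if (frames_per_segment < 1) stop("frames_per_segment must be >= 1")
  if (n_steps_per_frame < 1) stop("n_steps_per_frame must be >= 1")
  structure(list(dt = dt, temperature = temperature, friction = friction,
                 n_steps_per_frame = as.integer(n_steps_per_frame),
                 frames_per_segment = as.integer(frames_per_segment)),
            class = "dynamics_params")
}

#' Maxwell-Boltzmann velocity draw
#'
#' Each velocity component is an independent zero-mean Gaussian with variance
#' kBT / m_i. Fresh draws are the perturbation that decorrelates segments
#' restarted from the same snapshot.
#'
#' @param masses positive numeric vector.
#' @param temperature kBT (>= 0); 0 gives exactly zero velocities.
#' @param seed integer RNG seed.
#' @return length(masses) x 3 matrix of velocities.
#' @export
draw_mb_velocities <- function(masses, temperature, seed) {
  if (any(masses <= 0)) stop("masses must be > 0")
  if (temperature < 0) stop("temperature must be >= 0")
  n <- length(masses)
  if (temperature == 0) return(matrix(0, n, 3))
  set.seed(seed)
  matrix(stats::rnorm(3L * n), n, 3) * sqrt(temperature / masses)
}

#' Randomly arrange ligand copies around the binding site
#'
#' Places `n_copies` single-particle ligand copies uniformly at random in the
#' spherical shell `r_min <= |x - site_center| <= r_max`, rejecting
#' arrangements with any pairwise separation below `min_separation`, and adds
#' the frozen site marker as particle 1. Velocities are Maxwell-Boltzmann at
#' `temperature`. This is the reactant-construction step of the protocol: a
#' cloud of ligand copies around the relaxed receptor.
#'
#' @param spec a [toy_spec()].
#' @param n_copies number of ligand copies.
#' @param r_min,r_max shell radii (r_min >= excluded_radius,
#'   r_max <= confinement_radius).
#' @param min_separation minimum pairwise copy separation.
#' @param seed integer RNG seed.
#' @param temperature kBT for the initial velocity draw.
#' @param max_attempts rejection-sampling budget before a packing failure.
#' @return a [system_state()] with `n_copies + 1` particles (site marker
#'   first, copy_id 0).
#' @export
arrange_ligand_copies <- function(spec, n_copies, r_min, r_max,
                                  min_separation = 0, seed = 1,
                                  temperature = 1, max_attempts = 20000L) {
  stopifnot(inherits(spec, "toy_spec"), n_copies >= 1)
  if (r_min < spec$excluded_radius)
    stop("packing failure: r_min is inside the excluded core (r_min < excluded_radius)")
  if (r_max > spec$confinement_radius)
    stop("packing failure: r_max is outside the confinement wall (r_max > confinement_radius)")
  if (!(r_min <= r_max)) stop("packing failure: r_min must be <= r_max")
  set.seed(seed)
  placed <- matrix(NA_real_, n_copies, 3)
  k <- 0L
  attempts <- 0L
  while (k < n_copies) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(paste0("packing failure: could not place %d copies with ",
                          "min_separation = %g in shell [%g, %g] within %d ",
                          "attempts (pairwise-separation constraint violated)"),
                   n_copies, min_separation, r_min, r_max, max_attempts))
    # uniform in shell volume: direction isotropic, radius ~ r^2 density
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    r <- (r_min^3 + stats::runif(1) * (r_max^3 - r_min^3))^(1 / 3)
    x <- spec$site_center + r * u
    ok <- TRUE
    if (k > 0L && min_separation > 0) {
      d <- sqrt(rowSums((placed[seq_len(k), , drop = FALSE] -
                           matrix(x, k, 3, byrow = TRUE))^2))
      ok <- all(d >= min_separation)
    }
    if (ok) {
      k <- k + 1L
      placed[k, ] <- x
    }
  }
  pos <- rbind(matrix(spec$site_center, 1, 3), placed)
  masses <- rep(1, n_copies + 1L)
  vel <- draw_mb_velocities(masses, temperature,
                            derive_seed(seed, "arrange-velocities"))
  vel[1, ] <- 0
  system_state(pos, vel, masses, copy_id = 0:n_copies)
}

#' Planar hexagonal multi-site ligand copy
#'
#' Returns the coordinates of a benzene-like rigid ring of six sites with the
#' given circumradius, centred at `center`, lying in the xy-plane. Used to
#' exercise extended-ligand reaction coordinates (COM distance, radius of
#' gyration, distance-matrix scores) on multi-site copies.
#'
#' @param center 3-vector ring centre.
#' @param circumradius distance of each site from the centre.
#' @return 6 x 3 coordinate matrix.
#' @export
ring_copy_coords <- function(center = c(0, 0, 0), circumradius = 1) {
  ang <- 2 * pi * (0:5) / 6
  cbind(center[1] + circumradius * cos(ang),
        center[2] + circumradius * sin(ang),
        center[3] + 0 * ang)
}

#' Potential energy of a configuration
#' @param state a [system_state()].
#' @param spec a [toy_spec()].
#' @return scalar energy (kBT units).
#' @export
toy_energy <- function(state, spec) {
  .toy_energy_cpp(state$positions, state$copy_id, spec)
}

#' Forces on all particles
#'
#' Negative gradient of [toy_energy()]; frozen site-marker rows are zero.
#' @inheritParams toy_energy
#' @return n x 3 force matrix.
#' @export
toy_force <- function(state, spec) {
  .toy_force_cpp(state$positions, state$copy_id, spec)
}

#' Run one short Langevin segment
#'
#' Integrates the state with the BAOAB splitting of Langevin dynamics for
#' `frames_per_segment * n_steps_per_frame` steps, recording one snapshot
#' every `n_steps_per_frame` steps. The input state is not modified; the
#' trajectory is fully determined by `seed`.
#'
#' @param state starting [system_state()].
#' @param spec a [toy_spec()].
#' @param params a [dynamics_params()].
#' @param seed integer RNG seed for the thermal noise stream.
#' @param cycle,replica provenance labels stored on the returned snapshots.
#' @return list of `frames_per_segment` snapshots; each is a list with
#'   elements `state`, `cycle`, `replica`, `frame` (1-based within segment).
#' @export
run_segment <- function(state, spec, params, seed, cycle = 0L, replica = 1L) {
  stopifnot(inherits(state, "system_state"), inherits(spec, "toy_spec"),
            inherits(params, "dynamics_params"))
  set.seed(seed)
  out <- .run_segment_cpp(state$positions, state$velocities, state$masses,
                          state$copy_id, spec, params$dt, params$temperature,
                          params$friction, params$n_steps_per_frame,
                          params$frames_per_segment)
  lapply(seq_len(params$frames_per_segment), function(f) {
    snapshot(system_state(out$positions[[f]], out$velocities[[f]],
                          state$masses, state$copy_id),
             cycle = cycle, replica = replica, frame = f)
  })
}

#' Sample a long equilibrium trajectory
#'
#' Same integrator as [run_segment()], but returns flat per-frame position and
#' velocity matrices (one row per frame, 3 columns per particle) instead of
#' snapshot objects, which keeps runs of 1e5+ frames cheap. Used for
#' equilibrium statistics: equipartition, positional variance, Boltzmann
#' histograms.
#'
#' @inheritParams run_segment
#' @param n_frames number of frames to record.
#' @return list with `positions` and `velocities`, each `n_frames` x `3n`.
#' @export
sample_trajectory <- function(state, spec, params, n_frames, seed) {
  set.seed(seed)
  .run_trajectory_cpp(state$positions, state$velocities, state$masses,
                      state$copy_id, spec, params$dt, params$temperature,
                      params$friction, params$n_steps_per_frame,
                      as.integer(n_frames))
}

#' Construct a snapshot (a stored state with provenance)
#' @param state a [system_state()].
#' @param cycle,replica,frame provenance indices.
#' @param rc optional cached reaction-coordinate value.
#' @return an object of class `pacs_snapshot`.
#' @export
snapshot <- function(state, cycle = 0L, replica = 1L, frame = 1L, rc = NULL) {
  structure(list(state = state, cycle = as.integer(cycle),
                 replica = as.integer(replica), frame = as.integer(frame),
                 rc = rc),
            class = "pacs_snapshot")
}
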