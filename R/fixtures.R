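#' Ready-to-run desk-scale fixtures
#'
#' Four named systems exercise every stage of the package without external
#' data:
#' \describe{
#'   \item{funnel-easy}{a shallow funnel in a small confinement; plain
#'     dynamics reaches the binding cutoff on its own. Good for smoke tests
#'     and demonstrations.}
#'   \item{funnel-hard}{a narrow funnel at the core of a much larger
#'     confinement with slow (high-friction) diffusion, calibrated so that
#'     plain dynamics rarely reaches the cutoff within the cascade's total
#'     step budget while the selection loop does. This is the system on which
#'     the enrichment of adaptive selection over brute-force dynamics is
#'     measured.}
#'   \item{double-well-1d}{an analytic one-dimensional two-basin potential
#'     with a known basin free-energy difference (quartic barrier plus a
#'     smooth-step offset), sampled by its own vectorised Langevin walker;
#'     the Boltzmann oracle for the MSM free-energy pipeline.}
#'   \item{markov-2state}{synthetic discrete trajectories from a two-state
#'     Markov chain with stated transition probabilities; the closed-form
#'     oracle for counting, estimation and implied timescales.}
#' }
#'
#' @param name fixture name.
#' @param seed integer seed; a fixture is fully determined by (name, seed).
#' @param ... fixture-specific overrides (e.g. `p01`, `p10`, `delta_U`,
#'   `n_copies`).
#' @return a list whose contents depend on the fixture (see Details); the
#'   funnel fixtures return a full `pacs_config` plus the assembled engine
#'   and initial state.
#' @export
make_fixture <- function(name, seed = 1, ...) {
  switch(name,
    "funnel-easy" = funnel_fixture(seed, hard = FALSE, ...),
    "funnel-hard" = funnel_fixture(seed, hard = TRUE, ...),
    "double-well-1d" = double_well_fixture(seed, ...),
    "markov-2state" = markov2_fixture(seed, ...),
    stop("unknown fixture '", name, "'"))
}

funnel_fixture <- function(seed, hard, n_copies = 6L, max_cycles = NULL) {
  if (hard) {
    sys <- toy_spec(site_center = c(0, 0, 0), well_depth = 8, well_width = 1.2,
                    excluded_radius = 1.5, confinement_radius = 15,
                    copy_repulsion_strength = 2, copy_repulsion_range = 1,
                    wall_stiffness = 50, confinement_stiffness = 5)
    dyn <- dynamics_params(dt = 0.02, temperature = 1, friction = 40,
                           n_steps_per_frame = 5, frames_per_segment = 10)
    arrangement <- list(n_copies = n_copies, r_min = 10, r_max = 13,
                        min_separation = 2)
    cutoff <- 2.0
    max_cycles <- max_cycles %||% 50L
  } else {
    sys <- toy_spec(site_center = c(0, 0, 0), well_depth = 6, well_width = 1.5,
                    excluded_radius = 1, confinement_radius = 6,
                    copy_repulsion_strength = 2, copy_repulsion_range = 1,
                    wall_stiffness = 50, confinement_stiffness = 5)
    dyn <- dynamics_params(dt = 0.02, temperature = 1, friction = 5,
                           n_steps_per_frame = 5, frames_per_segment = 10)
    arrangement <- list(n_copies = n_copies, r_min = 3.5, r_max = 5,
                        min_separation = 1.5)
    cutoff <- 1.8
    max_cycles <- max_cycles %||% 30L
  }
  sampling <- sampling_config(
    n_replicas = 10L, frames_per_segment = dyn$frames_per_segment,
    cutoff = cutoff, max_cycles = max_cycles, seed = seed,
    rc = rc_spec("d_com"), convergence_window = 5L, convergence_tol = 0.05,
    aggregation_threshold = 0.5, aggregation_policy = "none")
  config <- structure(list(system = sys, dynamics = dyn, sampling = sampling,
                           arrangement = arrangement),
                      class = "pacs_config")
  initial <- arrange_ligand_copies(
    sys, n_copies = arrangement$n_copies, r_min = arrangement$r_min,
    r_max = arrangement$r_max, min_separation = arrangement$min_separation,
    seed = derive_seed(seed, "arrange"), temperature = dyn$temperature)
  engine <- toy_engine_adapter(sys, dyn,
                               arrange_shell = c(arrangement$r_min,
                                                 arrangement$r_max),
                               min_separation = arrangement$min_separation)
  list(name = if (hard) "funnel-hard" else "funnel-easy", config = config,
       system = sys, dynamics = dyn, sampling = sampling,
       arrangement = arrangement, initial = initial, engine = engine)
}

# smooth-step offset keeps the two wells mirror-shaped to ~1e-2, so the
# basin free-energy split is essentially the stated offset
dw_potential <- function(x, h = 2, delta_U = 2, w = 0.2) {
  h * (x^2 - 1)^2 + (delta_U / 2) * tanh(x / w)
}

dw_force <- function(x, h = 2, delta_U = 2, w = 0.2) {
  -(4 * h * x * (x^2 - 1) + (delta_U / 2) / (w * cosh(x / w)^2))
}

#' Analytic basin free-energy difference of the 1-D double well
#'
#' Computes -kBT ln(Z_right / Z_left) by quadrature of the Boltzmann weight
#' over each basin (split at the barrier top x = 0). Positive when the right
#' basin (positive offset) is less populated.
#'
#' @param h barrier-height parameter of the quartic (default 2, giving a
#'   slowest relaxation time far shorter than the default sampling length).
#' @param delta_U energy offset between the wells (kBT).
#' @param kBT thermal energy.
#' @return scalar free-energy difference F_right - F_left.
#' @export
double_well_delta_F <- function(h = 2, delta_U = 2, kBT = 1) {
  zl <- stats::integrate(function(x) exp(-dw_potential(x, h, delta_U) / kBT),
                         -4, 0, rel.tol = 1e-10)$value
  zr <- stats::integrate(function(x) exp(-dw_potential(x, h, delta_U) / kBT),
                         0, 4, rel.tol = 1e-10)$value
  -kBT * log(zr / zl)
}

double_well_fixture <- function(seed, h = 2, delta_U = 2) {
  sample_segments <- function(n_walkers = 20, n_frames = 2000,
                              n_steps_per_frame = 5, dt = 0.02,
                              friction = 2, kBT = 1, burn_in = 1000,
                              seed2 = seed) {
    set.seed(seed2)
    # start from the basin Boltzmann split so no burn-in bias survives
    p_right <- 1 / (1 + exp(double_well_delta_F(h, delta_U, kBT) / kBT))
    x <- ifelse(stats::runif(n_walkers) < p_right, 1, -1) +
      0.1 * stats::rnorm(n_walkers)
    v <- stats::rnorm(n_walkers) * sqrt(kBT)
    c1 <- exp(-friction * dt)
    c2 <- sqrt(1 - c1^2) * sqrt(kBT)
    out <- matrix(NA_real_, n_frames, n_walkers)
    f <- dw_force(x, h, delta_U)
    for (fr in seq_len(burn_in + n_frames)) {
      for (s in seq_len(n_steps_per_frame)) {
        v <- v + 0.5 * dt * f
        x <- x + 0.5 * dt * v
        v <- c1 * v + c2 * stats::rnorm(n_walkers)
        x <- x + 0.5 * dt * v
        f <- dw_force(x, h, delta_U)
        v <- v + 0.5 * dt * f
      }
      if (fr > burn_in) out[fr - burn_in, ] <- x
    }
    lapply(seq_len(n_walkers), function(w) out[, w])
  }
  sample_result <- function(n_cycles = 4, n_replicas = 10, n_frames = 1000,
                            ...) {
    segs <- sample_segments(n_walkers = n_cycles * n_replicas,
                            n_frames = n_frames, ...)
    cycles <- lapply(seq_len(n_cycles), function(cyc) {
      idx <- ((cyc - 1) * n_replicas + 1):(cyc * n_replicas)
      rc <- unlist(segs[idx])
      prov <- data.frame(cycle = cyc,
                         replica = rep(seq_len(n_replicas), each = n_frames),
                         frame = rep(seq_len(n_frames), n_replicas),
                         rc = rc)
      prov$id <- snap_id(prov$cycle, prov$replica, prov$frame)
      list(cycle_index = cyc, rc_values = rc, provenance = prov,
           selected = character(0), best_rc_this_cycle = min(rc),
           best_rc_so_far = min(rc))
    })
    structure(list(cycles = cycles, table = NULL, parents = list(),
                   termination_reason = "max_cycles",
                   config = sampling_config(n_replicas = n_replicas,
                                            max_cycles = n_cycles,
                                            seed = seed,
                                            rc = rc_spec("d_com")),
                   archive = NULL),
              class = "pacs_result")
  }
  list(name = "double-well-1d", h = h, delta_U = delta_U,
       potential = function(x) dw_potential(x, h, delta_U),
       force = function(x) dw_force(x, h, delta_U),
       delta_F = double_well_delta_F(h, delta_U),
       sample_segments = sample_segments,
       sample_result = sample_result)
}

markov2_fixture <- function(seed, p01 = 0.1, p10 = 0.1) {
  P <- matrix(c(1 - p01, p01, p10, 1 - p10), 2, 2, byrow = TRUE)
  generate <- function(n_segments = 10, len = 1000, seed2 = seed) {
    set.seed(seed2)
    segs <- lapply(seq_len(n_segments), function(i) {
      s <- integer(len)
      s[1] <- sample(1:2, 1)
      u <- stats::runif(len - 1)
      for (t in 2:len)
        s[t] <- if (u[t - 1] < P[s[t - 1], 1]) 1L else 2L
      s
    })
    structure(list(segments = segs, n_states = 2L,
                   centers = matrix(c(0, 1), 2, 1)),
              class = "discrete_trajectories")
  }
  list(name = "markov-2state", P = P, p01 = p01, p10 = p10,
       pi = c(p10, p01) / (p01 + p10),
       t2 = function(lag = 1) -lag / log(1 - p01 - p10),
       generate = generate)
}
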