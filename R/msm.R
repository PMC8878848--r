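#' Assign frames to microstates by k-means
#'
#' Clusters reaction-coordinate values (scalars or vectors) into `k`
#' microstates with k-means (k-means++ seeding, Lloyd iterations) and maps
#' every frame of every segment to its nearest centre. Segments are never
#' concatenated: each keeps its (cycle, replica) origin so no spurious
#' transitions are counted across restarts.
#'
#' @param rc_segments list of numeric vectors (or matrices, frames in rows),
#'   one per trajectory segment.
#' @param k number of microstates.
#' @param seed RNG seed for the initialisation.
#' @param iter_max maximum Lloyd iterations.
#' @return an object of class `discrete_trajectories`: integer segments,
#'   `n_states`, and the `centers` matrix (one row per microstate).
#' @export
cluster_microstates <- function(rc_segments, k, seed = 1, iter_max = 500L) {
  mats <- lapply(rc_segments, function(s) {
    m <- as.matrix(s)
    storage.mode(m) <- "double"
    m
  })
  X <- do.call(rbind, mats)
  ndistinct <- nrow(unique(X))
  if (k > ndistinct)
    stop(sprintf("k = %d exceeds the %d distinct data points", k, ndistinct))
  set.seed(seed)
  centers <- kmeanspp_init(X, k)
  km <- if (k == 1L)
    list(centers = matrix(colMeans(X), 1), cluster = rep(1L, nrow(X)))
  else
    tryCatch(
      stats::kmeans(X, centers = centers, iter.max = iter_max,
                    algorithm = "Lloyd"),
      error = function(e)  # Lloyd can abort on an emptied cluster
        stats::kmeans(X, centers = centers, iter.max = iter_max,
                      algorithm = "MacQueen"),
      warning = function(w)
        suppressWarnings(stats::kmeans(X, centers = centers,
                                       iter.max = iter_max,
                                       algorithm = "Lloyd")))
  lens <- vapply(mats, nrow, integer(1))
  idx <- split(km$cluster, rep(seq_along(mats), lens))
  segs <- lapply(idx, function(v) as.integer(unname(v)))
  names(segs) <- names(rc_segments)
  structure(list(segments = segs, n_states = as.integer(k),
                 centers = km$centers),
            class = "discrete_trajectories")
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- d2 / sum(d2)
    pick <- sample.int(n, 1, prob = p)
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  unique(centers)
}

#' Sliding-window transition counts
#'
#' For each segment, every ordered pair of frames `lag` apart increments the
#' count matrix; pairs never span two segments.
#'
#' @param dtrajs a [cluster_microstates()] result (or a list with `segments`
#'   and `n_states`).
#' @param lag lag time in frames (>= 1).
#' @return n_states x n_states count matrix.
#' @export
count_transitions <- function(dtrajs, lag) {
  if (lag < 1) stop("lag must be >= 1")
  n <- dtrajs$n_states
  C <- matrix(0, n, n)
  for (s in dtrajs$segments) {
    L <- length(s)
    if (L <= lag) next
    from <- s[1:(L - lag)]
    to <- s[(1 + lag):L]
    tab <- table(factor(from, levels = 1:n), factor(to, levels = 1:n))
    C <- C + unclass(tab)
  }
  dimnames(C) <- NULL
  C
}

largest_connected_set <- function(C, reversible) {
  n <- nrow(C)
  A <- if (reversible) (C + t(C)) > 0 else C > 0
  # label strongly connected components by repeated reachability
  reach <- function(A) {
    R <- A | diag(TRUE, nrow(A))
    repeat {
      R2 <- R | (R %*% R > 0)
      if (identical(R2, R)) return(R)
      R <- R2
    }
  }
  R <- reach(A)
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cid <- cid + 1L
    comp[R[i, ] & R[, i]] <- cid
  }
  sizes <- vapply(seq_len(cid), function(k) sum(C[comp == k, comp == k]), numeric(1))
  members <- which(comp == which.max(sizes))
  attr(members, "components") <- split(seq_len(n), comp)
  members
}

#' Maximum-likelihood transition matrix from counts
#'
#' Non-reversible: plain row normalisation of the counts. Reversible: the
#' symmetrised-count estimator T_ij = (c_ij + c_ji) / sum_j (c_ij + c_ji),
#' which satisfies detailed balance exactly with stationary weights
#' proportional to the row sums of C + C'. Reversible estimation is restricted
#' to the largest connected set of states (detailed balance needs one ergodic
#' block); non-reversible estimation drops only states without outgoing
#' counts. Retained states are reported in the `active_set` attribute, with a
#' warning when any state is dropped.
#'
#' @param counts square non-negative count matrix.
#' @param reversible impose detailed balance?
#' @return row-stochastic matrix over the active set, with attribute
#'   `active_set` (indices into the original states).
#' @export
estimate_T <- function(counts, reversible = TRUE) {
  C <- as.matrix(counts)
  if (nrow(C) != ncol(C) || any(C < 0)) stop("counts must be square and non-negative")
  # reversible estimation needs one connected block; plain maximum likelihood
  # only needs every retained state to have outgoing counts
  keep <- if (reversible) largest_connected_set(C, reversible = TRUE)
          else which(rowSums(C) > 0)
  if (sum(C[keep, keep, drop = FALSE]) == 0)
    stop("empty connected set: no transitions to estimate from")
  if (length(keep) < nrow(C))
    warning(sprintf("dropping %d state(s) outside the largest connected set",
                    nrow(C) - length(keep)))
  C <- C[keep, keep, drop = FALSE]
  Ceff <- if (reversible) C + t(C) else C
  rs <- rowSums(Ceff)
  if (any(rs == 0)) stop("state with no outgoing counts inside connected set")
  T_ <- Ceff / rs
  attr(T_, "active_set") <- as.integer(keep)
  T_
}

#' Implied relaxation timescales of a transition matrix
#'
#' t_i = -lag / ln(lambda_i) for the eigenvalues of T sorted descending in
#' modulus, excluding the stationary eigenvalue (lambda_1 = 1). Complex or
#' non-positive eigenvalues have no timescale interpretation and are returned
#' as `NA`; eigenvalues within numerical tolerance of 1 give `Inf`.
#'
#' @param T_ row-stochastic matrix.
#' @param lag lag time used to estimate `T_` (same frame units).
#' @return numeric vector of length nrow(T_) - 1.
#' @export
implied_timescales <- function(T_, lag = 1) {
  ev <- eigen(T_, only.values = TRUE)$values
  ev <- ev[order(Mod(ev), decreasing = TRUE)][-1]
  vapply(ev, function(l) {
    if (abs(Im(l)) > 1e-10) return(NA_real_)
    lr <- Re(l)
    if (lr >= 1 - 1e-12) return(Inf)
    if (lr <= 0) return(NA_real_)
    -lag / log(lr)
  }, numeric(1))
}

#' Select a lag time from the implied-timescale plateau
#'
#' Estimates the slowest implied timescale at every lag of the grid and
#' returns the smallest lag whose timescale changes by less than
#' `plateau_tol` (relative) versus the next grid point. Convergence of the
#' implied timescale in lag is the usual check that the discretised dynamics
#' is approximately Markovian. If no lag satisfies the test, the largest grid
#' lag is returned with a warning.
#'
#' @param dtrajs a [cluster_microstates()] result.
#' @param lag_grid increasing integer lags.
#' @param plateau_tol relative-change threshold.
#' @param reversible passed to [estimate_T()].
#' @return selected lag, with attribute `timescales` (slowest timescale per
#'   grid lag).
#' @export
select_lag <- function(dtrajs, lag_grid = c(1, 2, 5, 10), plateau_tol = 0.1,
                       reversible = TRUE) {
  if (is.unsorted(lag_grid, strictly = TRUE)) stop("lag_grid must be increasing")
  ts <- vapply(lag_grid, function(l) {
    C <- count_transitions(dtrajs, l)
    if (sum(C) == 0) return(NA_real_)
    T_ <- suppressWarnings(estimate_T(C, reversible = reversible))
    it <- implied_timescales(T_, l)
    it <- it[is.finite(it)]
    if (length(it) == 0) NA_real_ else max(it)
  }, numeric(1))
  if (all(is.na(ts))) stop("no lag in the grid yields a defined implied timescale")
  if (length(lag_grid) == 1L)
    return(structure(lag_grid, timescales = ts))
  for (i in seq_len(length(lag_grid) - 1L)) {
    if (is.na(ts[i]) || is.na(ts[i + 1])) next
    if (abs(ts[i + 1] - ts[i]) / ts[i] < plateau_tol)
      return(structure(lag_grid[i], timescales = ts))
  }
  warning("no implied-timescale plateau in the lag grid; using the largest lag")
  structure(lag_grid[length(lag_grid)], timescales = ts)
}

#' Stationary distribution of a transition matrix
#'
#' The left eigenvector of eigenvalue 1, normalised to sum to one. The matrix
#' must be irreducible (one connected block); otherwise the disconnected
#' blocks are reported in the error.
#'
#' @param T_ row-stochastic matrix.
#' @return probability vector pi with pi T = pi.
#' @export
stationary_distribution <- function(T_) {
  keep <- largest_connected_set(T_ > 0, reversible = FALSE)
  if (length(keep) < nrow(T_)) {
    blocks <- attr(keep, "components")
    stop("transition matrix is reducible; blocks: ",
         paste(vapply(blocks, function(b) paste0("{", paste(b, collapse = ","), "}"),
                      character(1)), collapse = " "))
  }
  ev <- eigen(t(T_))
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  v <- v / sum(v)
  v[v < 0 & v > -1e-12] <- 0
  if (any(v < 0)) stop("stationary eigenvector has negative entries")
  v / sum(v)
}

#' Free-energy profile from a stationary distribution
#'
#' F_i = -kBT ln(pi_i / max_k pi_k): the origin is pinned to the most
#' populated microstate, so min(F) = 0 exactly. Zero-probability states get
#' `Inf`.
#'
#' @param pi probability vector.
#' @param kBT thermal energy scale.
#' @return numeric free energies.
#' @export
free_energy_profile <- function(pi, kBT = 1) {
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("pi must be a probability vector")
  F <- -kBT * log(pi / max(pi))
  F[pi == 0] <- Inf
  F
}

#' Full Markov-state-model pipeline on reaction-coordinate segments
#'
#' Clusters the frames into microstates, selects a lag from the
#' implied-timescale plateau, estimates a reversible transition matrix under
#' detailed balance, and converts its stationary distribution into a
#' free-energy profile along the coordinate.
#'
#' @param rc_segments list of numeric vectors, one per independent segment.
#' @param k number of microstates.
#' @param lag_grid candidate lags (frames).
#' @param kBT thermal energy scale.
#' @param seed clustering seed.
#' @param plateau_tol relative plateau tolerance for [select_lag()].
#' @return an object of class `transition_model` with elements `lag`,
#'   `counts`, `T`, `pi`, `timescales`, `free_energy`, `centers`,
#'   `active_set`, `kBT`, and `profile` — a data frame (rc_center, F, pi)
#'   sorted ascending in the coordinate; dropped states carry `NA`.
#' @export
msm_profile <- function(rc_segments, k = 30, lag_grid = c(1, 2, 5, 10),
                        kBT = 1, seed = 1, plateau_tol = 0.1) {
  dtrajs <- cluster_microstates(rc_segments, k, seed = seed)
  lag <- if (k == 1L) lag_grid[1]  # one state: no relaxation to converge
         else select_lag(dtrajs, lag_grid, plateau_tol = plateau_tol)
  C <- count_transitions(dtrajs, lag)
  T_ <- suppressWarnings(estimate_T(C, reversible = TRUE))
  act <- attr(T_, "active_set")
  pi_act <- stationary_distribution(T_)
  F_act <- free_energy_profile(pi_act, kBT)
  pi_full <- rep(NA_real_, k); pi_full[act] <- pi_act
  F_full <- rep(NA_real_, k); F_full[act] <- F_act
  centers1 <- dtrajs$centers[, 1]
  prof <- data.frame(rc_center = centers1, F = F_full, pi = pi_full)
  prof <- prof[order(prof$rc_center), ]
  rownames(prof) <- NULL
  structure(list(lag = as.integer(lag), counts = C, T = T_, pi = pi_act,
                 timescales = implied_timescales(T_, lag),
                 free_energy = F_act, centers = dtrajs$centers,
                 active_set = act, kBT = kBT, dtrajs = dtrajs,
                 profile = prof),
            class = "transition_model")
}

#' Free-energy profile along a reaction coordinate from a cascade run
#'
#' Projects every stored frame of a [run_pacs()] result onto the coordinate
#' (by default the one the run was ranked on), keeping the per-(cycle,
#' replica) segment structure, and runs the MSM pipeline on the projection.
#' Because cascade selection biases where segments start, the resulting
#' profile is a survey of the sampled pathway, not an exact equilibrium free
#' energy; on unbiased equilibrium data it converges to the Boltzmann result.
#'
#' @param result a [run_pacs()] result (>= 2 cycles).
#' @param rc optional [rc_spec()] to re-project onto (requires the snapshot
#'   archive); NULL reuses the run's ranking coordinate values.
#' @inheritParams msm_profile
#' @return a `transition_model` (see [msm_profile()]).
#' @export
profile_along_rc <- function(result, rc = NULL, k = 30,
                             lag_grid = c(1, 2, 5, 10), kBT = 1, seed = 1,
                             plateau_tol = 0.1) {
  if (length(result$cycles) < 2)
    stop("profile_along_rc requires a run of >= 2 cycles")
  segs <- list()
  for (rec in result$cycles) {
    prov <- rec$provenance
    for (r in unique(prov$replica)) {
      rows <- prov$replica == r
      vals <- if (is.null(rc)) prov$rc[rows] else {
        if (is.null(result$archive))
          stop("re-projection onto another rc requires keep_snapshots = TRUE")
        pool <- result$archive[[rec$cycle_index]]
        evaluate_rc_pool(pool[which(rows)], rc)
      }
      segs[[sprintf("c%d.r%d", rec$cycle_index, r)]] <- vals
    }
  }
  kk <- min(k, nrow(unique(as.matrix(unlist(segs)))))
  msm_profile(segs, k = kk, lag_grid = lag_grid, kBT = kBT, seed = seed,
              plateau_tol = plateau_tol)
}
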