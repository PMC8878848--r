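dtraj <- function(..., n = 2L) {
  structure(list(segments = lapply(list(...), as.integer), n_states = n,
                 centers = matrix(seq_len(n) - 1, n, 1)),
            class = "discrete_trajectories")
}

test_that("transition counting follows the sliding window and segment boundaries", {
  expect_equal(count_transitions(dtraj(c(1, 1, 2, 2)), 1),
               matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE))
  # lag >= segment length: zero matrix
  expect_equal(count_transitions(dtraj(c(1, 2), c(2, 1)), 5), matrix(0, 2, 2))
  # total counts = sum over segments of max(0, len - lag)
  set.seed(2)
  segs <- lapply(c(10, 3, 7, 1), function(L) sample(1:3, L, replace = TRUE))
  d3 <- structure(list(segments = segs, n_states = 3L, centers = matrix(0:2)),
                  class = "discrete_trajectories")
  for (lag in c(1, 2, 4))
    expect_equal(sum(count_transitions(d3, lag)),
                 sum(pmax(0, lengths(segs) - lag)))
  # never concatenates across segments: compare with explicit oracle
  expect_equal(count_transitions(d3, 2), count_oracle(segs, 3, 2))
})

test_that("transition-matrix estimators: row normalisation and detailed balance", {
  C <- matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(estimate_T(C, reversible = FALSE),
               matrix(c(0.5, 0.5, 0, 1), 2, 2, byrow = TRUE),
               ignore_attr = TRUE)

  Csym <- matrix(c(4, 2, 2, 6), 2, 2, byrow = TRUE)
  expect_equal(estimate_T(Csym, TRUE), estimate_T(Csym, FALSE),
               ignore_attr = TRUE)

  Cr <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE)
  Tr <- estimate_T(Cr, reversible = TRUE)
  pi <- stationary_distribution(Tr)
  flux <- pi * Tr
  expect_lt(max(abs(flux - t(flux))), 1e-12)

  # disconnected extra state is trimmed with a warning
  C3 <- rbind(cbind(Cr, 0), 0)
  expect_warning(T3 <- estimate_T(C3, TRUE), "largest connected set")
  expect_identical(attr(T3, "active_set"), 1:2)
  expect_equal(unclass(T3), unclass(Tr), ignore_attr = TRUE)
})

test_that("implied timescales follow -lag/ln(lambda)", {
  T1 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  expect_equal(implied_timescales(T1, 1), -1 / log(0.8), tolerance = 1e-12)
  # lambda2 = exp(-1) forces t2 = 1
  l2 <- exp(-1)
  T2 <- matrix(c((1 + l2) / 2, (1 - l2) / 2, (1 - l2) / 2, (1 + l2) / 2), 2, 2)
  expect_equal(implied_timescales(T2, 1), 1, tolerance = 1e-12)
  # identity: all eigenvalues 1, timescales infinite
  expect_equal(implied_timescales(diag(3), 1), c(Inf, Inf))
  # lag scaling
  expect_equal(implied_timescales(T1, 5), -5 / log(0.8))
})

test_that("stationary distributions match closed forms and defining property", {
  Ts <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  expect_equal(stationary_distribution(Ts), c(0.5, 0.5))

  Tab <- matrix(c(0.8, 0.2, 0.1, 0.9), 2, 2, byrow = TRUE)
  expect_equal(stationary_distribution(Tab), c(1, 2) / 3, tolerance = 1e-12)

  set.seed(4)
  for (i in 1:5) {
    C <- matrix(rpois(25, 5) + 1, 5, 5)
    T_ <- estimate_T(C, reversible = TRUE)
    pi <- stationary_distribution(T_)
    expect_lt(max(abs(pi %*% T_ - pi)), 1e-10)
    expect_equal(sum(pi), 1)
  }

  Tred <- diag(2)
  expect_error(stationary_distribution(Tred), "reducible.*\\{1\\}")
})

test_that("free energies are pinned to zero at the most populated state", {
  expect_equal(free_energy_profile(rep(0.25, 4)), rep(0, 4))
  expect_equal(free_energy_profile(c(0.8, 0.2)), c(0, log(4)))
  expect_equal(free_energy_profile(c(0.8, 0.2), kBT = 2), c(0, 2 * log(4)))
  set.seed(6)
  p <- runif(7); p <- p / sum(p)
  F <- free_energy_profile(p)
  expect_equal(min(F), 0)
  expect_equal(which.min(F), which.max(p))
  expect_error(free_energy_profile(c(0.6, 0.6)), "probability")
})

test_that("k-means microstates separate well-separated populations", {
  segs <- list(c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1)))
  dt <- cluster_microstates(segs, 2, seed = 1)
  s <- dt$segments[[1]]
  expect_length(unique(s[1:50]), 1)
  expect_length(unique(s[51:100]), 1)
  expect_false(s[1] == s[51])

  one <- cluster_microstates(segs, 1, seed = 1)
  expect_true(all(one$segments[[1]] == 1))
  expect_equal(one$centers[1, 1], mean(segs[[1]]))

  # each frame sits with its nearest centre
  set.seed(8)
  rnd <- list(rnorm(200), rnorm(100, 3))
  dt2 <- cluster_microstates(rnd, 5, seed = 2)
  x <- unlist(rnd)
  lab <- unlist(dt2$segments)
  nearest <- apply(abs(outer(x, dt2$centers[, 1], `-`)), 1, which.min)
  expect_identical(lab, as.integer(nearest))

  expect_error(cluster_microstates(list(c(1, 1, 2)), 3), "distinct")
})

test_that("segments keep their origin: no transitions across restarts", {
  segs <- list(rep(1L, 10), rep(2L, 10))
  dt <- dtraj(rep(1, 10), rep(2, 10))
  C <- count_transitions(dt, 1)
  expect_equal(C[1, 2], 0)
  expect_equal(C[2, 1], 0)
})

test_that("lag selection finds the plateau of a genuinely Markovian chain", {
  fx <- make_fixture("markov-2state", seed = 3, p01 = 0.1, p10 = 0.1)
  dtr <- fx$generate(20, 2000)
  lag <- select_lag(dtr, c(1, 2, 5, 10), plateau_tol = 0.1)
  expect_equal(as.integer(lag), 1L)
  ts <- attr(lag, "timescales")
  expect_equal(ts[1], fx$t2(1), tolerance = 0.1)

  expect_equal(as.integer(select_lag(dtr, c(2, 5), plateau_tol = Inf)), 2L)
  expect_equal(as.integer(select_lag(dtr, 5, plateau_tol = 0.1)), 5L)
  expect_error(select_lag(dtr, c(5, 2), plateau_tol = 0.1), "increasing")
})

test_that("estimation converges to the true chain as data grows", {
  fx <- make_fixture("markov-2state", seed = 11, p01 = 0.15, p10 = 0.05)
  err <- function(len, seed2) {
    dtr <- fx$generate(10, len, seed2 = seed2)
    T_ <- estimate_T(count_transitions(dtr, 1), reversible = FALSE)
    max(abs(T_ - fx$P))
  }
  e1 <- mean(vapply(1:6, function(s) err(250, s), numeric(1)))
  e16 <- mean(vapply(1:6, function(s) err(4000, s), numeric(1)))
  expect_lt(e16, e1 * 0.5)   # 16x data: expect ~4x error drop; allow noise
})

test_that("the msm pipeline recovers a two-basin free-energy split", {
  fx <- make_fixture("double-well-1d", seed = 5)
  segs <- fx$sample_segments(n_walkers = 30, n_frames = 2000)
  m <- suppressWarnings(msm_profile(segs, k = 20, lag_grid = c(1, 5, 10)))
  expect_s3_class(m, "transition_model")
  expect_true(!is.unsorted(m$profile$rc_center))
  expect_equal(min(m$free_energy), 0)
  expect_lt(max(abs(rowSums(m$T) - 1)), 1e-10)
  right <- m$profile$rc_center > 0
  dF <- -log(sum(m$profile$pi[right], na.rm = TRUE) /
             sum(m$profile$pi[!right], na.rm = TRUE))
  expect_equal(dF, fx$delta_F, tolerance = 0.35)

  # constant single segment: one populated state at zero free energy
  const <- msm_profile(list(rep(2.5, 50)), k = 1, lag_grid = 1)
  expect_equal(const$pi, 1)
  expect_equal(const$free_energy, 0)
})
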