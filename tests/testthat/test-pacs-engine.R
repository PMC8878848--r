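make_pool <- function(rc, N = NULL, M = NULL) {
  n <- length(rc)
  if (is.null(N)) { N <- 1L; M <- n }
  data.frame(cycle = 1L, replica = rep(seq_len(N), each = M),
             frame = rep(seq_len(M), N), rc = rc,
             id = sprintf("c0001.r%03d.f%03d", rep(seq_len(N), each = M),
                          rep(seq_len(M), N)))
}

test_that("selection matches a full-sort oracle and breaks ties deterministically", {
  set.seed(9)
  for (i in 1:25) {
    rc <- round(runif(30), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
    pool <- make_pool(rc, N = 5L, M = 6L)
    sel <- rank_and_select(pool, 10)
    ord <- order(pool$rc, pool$replica, pool$frame)
    expect_identical(sel, pool$id[ord][1:10])
  }

  # all equal: first N in (replica, frame) order
  pool <- make_pool(rep(1, 12), N = 3L, M = 4L)
  expect_identical(rank_and_select(pool, 3),
                   c("c0001.r001.f001", "c0001.r001.f002", "c0001.r001.f003"))

  # recycling: pool of 3, select 5
  small <- make_pool(c(0.3, 0.1, 0.2))
  expect_identical(rank_and_select(small, 5),
                   small$id[c(2, 3, 1, 2, 3)])
  expect_error(rank_and_select(small[0, ], 2), "empty")
})

test_that("termination honours cutoff, convergence, and the cycle limit", {
  cfg <- sampling_config(cutoff = 4.0, max_cycles = 100, rc = rc_spec("d_com"),
                         convergence_window = 2, convergence_tol = 0.05)
  hist1 <- list(list(rc_values = c(5, 6, 7), best_rc_this_cycle = 3.7))
  expect_equal(check_termination(hist1, cfg), "cutoff")

  above <- list(list(rc_values = c(5, 6, 7), best_rc_this_cycle = 5))
  expect_equal(check_termination(above, cfg), "continue")

  # two identical consecutive windows: L1 distance zero < any tolerance
  rec <- list(rc_values = c(5, 5.5, 6, 6.5), best_rc_this_cycle = 5)
  expect_equal(check_termination(rep(list(rec), 4), cfg), "converged")

  cfg2 <- sampling_config(cutoff = NA, max_cycles = 3, rc = rc_spec("d_com"),
                          convergence_window = 0)
  expect_equal(check_termination(rep(list(rec), 3), cfg2), "max_cycles")
  expect_error(check_termination(list(), cfg), "at least one")
})

test_that("aggregation detection is single-linkage on copy COMs", {
  far <- snap_with_copies(rbind(c(5, 0, 0), c(0, 5, 0), c(0, 0, 5)))
  cl <- detect_aggregation(far, threshold = 2)
  expect_length(cl, 3)
  expect_false(attr(cl, "aggregated"))

  near <- snap_with_copies(rbind(c(5, 0, 0), c(6, 0, 0)))
  cl2 <- detect_aggregation(near, threshold = 2)
  expect_length(cl2, 1)
  expect_true(attr(cl2, "aggregated"))

  # chain A-B-C with d(A,B)=d(B,C)=1.5, d(A,C)=3: one cluster of three
  chain <- snap_with_copies(rbind(c(3, 0, 0), c(4.5, 0, 0), c(6, 0, 0)))
  cl3 <- detect_aggregation(chain, threshold = 2)
  expect_length(cl3, 1)
  expect_identical(sort(cl3[[1]]), 1:3)

  one <- snap_with_copies(rbind(c(5, 0, 0)))
  expect_error(detect_aggregation(one, 2), ">= 2")
})

test_that("the cycle loop does exact bookkeeping and is reproducible", {
  fx <- make_fixture("funnel-easy", seed = 8, n_copies = 2)
  cfg <- fx$sampling
  cfg$n_replicas <- 2L
  cfg$frames_per_segment <- 4L
  cfg$cutoff <- NA
  cfg$max_cycles <- 3L
  cfg$convergence_window <- 0L
  fx$engine$params$frames_per_segment <- 4L
  eng <- toy_engine_adapter(fx$system,
                            dynamics_params(dt = 0.02, friction = 5,
                                            n_steps_per_frame = 5,
                                            frames_per_segment = 4))
  res <- run_pacs(cfg, eng, fx$initial)
  expect_equal(res$termination_reason, "max_cycles")
  expect_length(res$cycles, 3)
  for (rec in res$cycles) expect_length(rec$rc_values, 8)

  res2 <- run_pacs(cfg, eng, fx$initial)
  expect_identical(lapply(res$cycles, `[[`, "rc_values"),
                   lapply(res2$cycles, `[[`, "rc_values"))

  # best-so-far is a running minimum: non-increasing
  best <- vapply(res$cycles, `[[`, numeric(1), "best_rc_so_far")
  expect_true(all(diff(best) <= 0))
})

test_that("a funnel run reaches its cutoff and back-traces coherent pathways", {
  fx <- make_fixture("funnel-easy", seed = 1)
  res <- run_pacs(fx$sampling, fx$engine, fx$initial)
  expect_equal(res$termination_reason, "cutoff")
  best <- vapply(res$cycles, `[[`, numeric(1), "best_rc_so_far")
  expect_true(all(diff(best) <= 0))
  expect_lt(min(best), fx$sampling$cutoff)

  paths <- trace_binding_paths(res)
  expect_gt(length(paths), 0)
  for (p in paths) {
    expect_identical(p$cycle[1], 0L)                  # starts at the reactant
    expect_true(all(diff(p$cycle) > 0))               # strictly increasing
    expect_lt(p$rc[nrow(p)], fx$sampling$cutoff)      # ends bound
    # every intermediate rc was actually observed in its cycle's pool
    for (i in 2:nrow(p)) {
      rec <- res$cycles[[p$cycle[i]]]
      expect_true(p$rc[i] %in% rec$rc_values)
    }
  }
})

test_that("per-copy ranking mode runs and still improves the coordinate", {
  fx <- make_fixture("funnel-easy", seed = 3)
  cfg <- fx$sampling
  cfg$rc <- rc_spec("d_com", copy_reduction = "per_copy")
  cfg$max_cycles <- 5L
  res <- run_pacs(cfg, fx$engine, fx$initial)
  best <- vapply(res$cycles, `[[`, numeric(1), "best_rc_so_far")
  expect_true(all(diff(best) <= 0))
})

test_that("aggregation reset re-randomises clustered copies but keeps the best", {
  fx <- make_fixture("funnel-easy", seed = 2)
  eng <- fx$engine
  # two copies on top of each other, one close to the site
  snap <- snap_with_copies(rbind(c(3, 0, 0), c(3.2, 0, 0), c(5, 0, 0)))
  moved <- eng$rearrange(snap, keep_copies = 1L, seed = 99)
  expect_equal(moved$state$positions[2, ], c(3, 0, 0))   # best copy untouched
  expect_false(isTRUE(all.equal(moved$state$positions[3, ], c(3.2, 0, 0))))
  radii <- sqrt(rowSums(moved$state$positions[3:4, ]^2))
  expect_true(all(radii >= fx$arrangement$r_min - 1e-9 &
                  radii <= fx$arrangement$r_max + 1e-9))

  # a run with the reset policy enabled stays valid end to end
  cfg <- fx$sampling
  cfg$aggregation_policy <- "reset"
  cfg$aggregation_threshold <- 1.0
  cfg$max_cycles <- 4L
  res <- run_pacs(cfg, eng, fx$initial)
  expect_true(res$termination_reason %in% c("cutoff", "max_cycles"))
})

test_that("checkpoint + resume state reproduces the uninterrupted run", {
  fx <- make_fixture("funnel-easy", seed = 6)
  cfg <- fx$sampling
  cfg$max_cycles <- 6L
  cfg$cutoff <- NA
  cfg$convergence_window <- 0L
  full <- run_pacs(cfg, fx$engine, fx$initial)
  part <- run_pacs(cfg, fx$engine, fx$initial, stop_after = 3)
  expect_equal(part$termination_reason, "checkpoint")
  expect_length(part$cycles, 3)
  seeds <- lapply(part$cycles[[3]]$selected, function(id) {
    i <- match(id, part$cycles[[3]]$provenance$id)
    part$archive[[3]][[i]]
  })
  ptab <- lapply(part$cycles, function(rec) {
    p <- rec$provenance
    p$selected <- p$id %in% rec$selected
    p
  })
  cont <- run_pacs(cfg, fx$engine, fx$initial,
                   .resume = list(cycles = part$cycles, parents = part$parents,
                                  archive = part$archive, pool_tab = ptab,
                                  seeds = seeds))
  expect_identical(lapply(full$cycles, `[[`, "rc_values"),
                   lapply(cont$cycles, `[[`, "rc_values"))
})
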