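test_that("ligand-copy arrangement respects the shell and separation constraints", {
  spec <- toy_spec(excluded_radius = 1, confinement_radius = 8)

  one <- arrange_ligand_copies(spec, 1, r_min = 2, r_max = 5, seed = 1)
  r <- sqrt(sum(one$positions[2, ]^2))
  expect_gte(r, 2); expect_lte(r, 5)

  six <- arrange_ligand_copies(spec, 6, r_min = 3, r_max = 6,
                               min_separation = 1.5, seed = 4)
  pd <- as.matrix(dist(six$positions[-1, ]))
  expect_true(all(pd[upper.tri(pd)] >= 1.5))
  radii <- sqrt(rowSums(six$positions[-1, ]^2))
  expect_true(all(radii >= 3 & radii <= 6))

  # identical seed reproduces the arrangement exactly
  six2 <- arrange_ligand_copies(spec, 6, r_min = 3, r_max = 6,
                                min_separation = 1.5, seed = 4)
  expect_identical(six$positions, six2$positions)
  expect_identical(six$velocities, six2$velocities)
})

test_that("infeasible packing fails with a constraint-naming error", {
  spec <- toy_spec(excluded_radius = 1, confinement_radius = 8)
  # 50 copies at pairwise separation >= 3 cannot fit in a thin shell of
  # radius ~4 (the sphere around the shell holds < 20 such copies)
  expect_error(
    arrange_ligand_copies(spec, 50, r_min = 3.9, r_max = 4.1,
                          min_separation = 3, seed = 1,
                          max_attempts = 2000),
    "packing failure.*separation")
  expect_error(arrange_ligand_copies(spec, 2, r_min = 0.5, r_max = 4, seed = 1),
               "excluded")
  expect_error(arrange_ligand_copies(spec, 2, r_min = 2, r_max = 9, seed = 1),
               "confinement")
})

test_that("forces are the exact negative gradient of the energy", {
  spec <- toy_spec(site_center = c(0.3, -0.2, 0.1), well_depth = 4,
                   well_width = 1.2, excluded_radius = 1,
                   confinement_radius = 4, copy_repulsion_strength = 2,
                   copy_repulsion_range = 1.5)
  set.seed(11)
  for (rep in 1:5) {
    st <- arrange_ligand_copies(spec, 4, r_min = 1, r_max = 3.9,
                                min_separation = 0.3, seed = rep)
    f <- toy_force(st, spec)
    h <- 1e-6
    for (i in 2:5) for (d in 1:3) {
      p1 <- st$positions; p1[i, d] <- p1[i, d] + h
      p2 <- st$positions; p2[i, d] <- p2[i, d] - h
      fd <- -(toy_energy(system_state(p1, st$velocities, st$masses, st$copy_id), spec) -
              toy_energy(system_state(p2, st$velocities, st$masses, st$copy_id), spec)) / (2 * h)
      expect_equal(f[i, d], fd, tolerance = 1e-6)
    }
  }
})

test_that("force is zero at the well centre and beyond the repulsion range", {
  spec <- toy_spec(copy_repulsion_range = 1, confinement_radius = 20)
  at_center <- snapshot(system_state(matrix(0, 1, 3), matrix(0, 1, 3), 1, 1L))
  expect_equal(toy_force(at_center$state, spec), matrix(0, 1, 3))

  # two copies far apart, far from walls and well: all forces ~ 0
  far <- system_state(rbind(c(10, 0, 0), c(10, 5, 0)), matrix(0, 2, 3),
                      c(1, 1), c(1L, 2L))
  f <- toy_force(far, spec)
  expect_lt(max(abs(f)), 1e-6)
})

test_that("zero-temperature dynamics at the minimum is a fixed point", {
  spec <- toy_spec()
  params <- dynamics_params(temperature = 0, frames_per_segment = 5)
  st <- system_state(matrix(0, 1, 3), matrix(0, 1, 3), 1, 1L)
  seg <- run_segment(st, spec, params, seed = 1)
  expect_length(seg, 5)
  for (sn in seg) expect_equal(sn$state$positions, st$positions)
})

test_that("segments record M frames with increasing indices and do not mutate input", {
  spec <- toy_spec()
  params <- dynamics_params(frames_per_segment = 7)
  st <- arrange_ligand_copies(spec, 2, r_min = 2, r_max = 5, seed = 3)
  pos_before <- st$positions + 0  # force a copy
  seg <- run_segment(st, spec, params, seed = 9, cycle = 2L, replica = 3L)
  expect_length(seg, 7)
  expect_identical(vapply(seg, function(s) s$frame, integer(1)), 1:7)
  expect_identical(vapply(seg, function(s) s$cycle, integer(1)), rep(2L, 7))
  expect_identical(st$positions, pos_before)
})

test_that("same seed gives bitwise-identical segments, different seeds differ", {
  spec <- toy_spec()
  params <- dynamics_params()
  st <- arrange_ligand_copies(spec, 3, r_min = 2, r_max = 5, seed = 5)
  a <- run_segment(st, spec, params, seed = 42)
  b <- run_segment(st, spec, params, seed = 42)
  c <- run_segment(st, spec, params, seed = 43)
  expect_identical(lapply(a, function(s) s$state$positions),
                   lapply(b, function(s) s$state$positions))
  expect_false(identical(a[[1]]$state$positions, c[[1]]$state$positions))
})

test_that("integration blow-up reports the failing step", {
  spec <- toy_spec(wall_stiffness = 1e8)
  params <- dynamics_params(dt = 10, temperature = 0)
  st <- system_state(matrix(c(0.5, 0, 0), 1, 3), matrix(0, 1, 3), 1, 1L)
  expect_error(run_segment(st, spec, params, seed = 1), "blow-up.*step")
})

test_that("Maxwell-Boltzmann draws have the right moments and determinism", {
  expect_equal(draw_mb_velocities(c(1, 2), 0, seed = 1), matrix(0, 2, 3))
  expect_error(draw_mb_velocities(c(1, -1), 1, seed = 1), "mass")

  n <- 1e5
  v <- draw_mb_velocities(rep(2, n), 1.5, seed = 7)
  # per-component variance kBT/m = 0.75, sd of sample variance ~ var*sqrt(2/n)
  se <- 0.75 * sqrt(2 / n)
  for (d in 1:3) expect_lt(abs(var(v[, d]) - 0.75), 3 * se)
  expect_lt(max(abs(colMeans(v))), 4 * sqrt(0.75 / n))

  expect_identical(draw_mb_velocities(rep(1, 10), 1, seed = 3),
                   draw_mb_velocities(rep(1, 10), 1, seed = 3))
  expect_false(identical(draw_mb_velocities(rep(1, 10), 1, seed = 3),
                         draw_mb_velocities(rep(1, 10), 1, seed = 4)))
})

test_that("state validation catches shape and mass errors", {
  expect_error(system_state(matrix(0, 2, 3), matrix(0, 1, 3), c(1, 1), c(1L, 2L)),
               "matching")
  expect_error(system_state(matrix(0, 2, 3), matrix(0, 2, 3), c(1, 0), c(1L, 2L)),
               "masses")
  expect_error(toy_spec(well_width = 0), "well_width")
  expect_error(dynamics_params(dt = 0), "dt")
})

test_that("the hexagonal ring copy has its circumradius as radius of gyration", {
  ring <- ring_copy_coords(center = c(1, 2, 3), circumradius = 1.4)
  expect_equal(center_of_mass(ring), c(1, 2, 3))
  expect_equal(radius_of_gyration(ring), 1.4)
})
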