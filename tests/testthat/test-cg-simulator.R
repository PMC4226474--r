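# Small-system configs keep these runs to seconds; the full-scale sweep
# lives in the acceptance tests.

test_that("linker-to-bead mapping and initial conformation contracts hold", {
  cfg <- sim_config(n_beads = 2, n_steps = 1000)
  sys <- build_chain(4000, cfg)
  expect_equal(sys$config$n_beads, 31L)          # round(90.9/3) + 1
  expect_equal(sys$config$segment_length, 3 * 0.28)
  expect_equal(sys$coords[1, ], c(0, 0, 9))      # fixed tether bead
  expect_equal(nrow(sys$coords), 31L)
  # bonds at rest length, no overlaps below sigma
  d <- sqrt(rowSums(diff(sys$coords)^2))
  expect_equal(d, rep(sys$config$segment_length, 30), tolerance = 1e-9)
  expect_true(all(sys$coords[, 3] > 0))

  dumbbell <- suppressWarnings(     # a dumbbell cannot reach the plane
    build_chain(NULL, sim_config(n_beads = 2, n_steps = 10)))
  expect_equal(nrow(dumbbell$coords), 2L)

  # determinism: identical seeds give identical initial coordinates
  a <- build_chain(4000, sim_config(n_beads = 2, n_steps = 10, seed = 7))
  b <- build_chain(4000, sim_config(n_beads = 2, n_steps = 10, seed = 7))
  expect_identical(a$coords, b$coords)

  # a chain too short to reach the binding zone is flagged
  expect_warning(build_chain(484, sim_config(n_beads = 2, n_steps = 10)),
                 "impossible")
})

test_that("config construction enforces the timestep resolution contract", {
  expect_error(sim_config(n_beads = 10, timestep = 0.1), "RMS displacement")
  expect_error(sim_config(n_beads = 1, n_steps = 10), "at least 2")
  expect_error(sim_config(n_beads = 10, tether_height = -1), "positive")
})

test_that("trajectories are bit-reproducible for a fixed seed", {
  cfg <- sim_config(n_beads = 8, n_steps = 2e4, n_replicas = 2,
                    equilibration_steps = 100, tether_height = 4, seed = 42)
  r1 <- run_brownian(build_chain(NULL, cfg))
  r2 <- run_brownian(build_chain(NULL, cfg))
  expect_identical(r1$heights, r2$heights)
  expect_identical(r1$seeds, r2$seeds)
  # different seed, different path
  cfg$seed <- 43L
  r3 <- run_brownian(build_chain(NULL, cfg))
  expect_false(identical(r1$heights$height, r3$heights$height))
})

test_that("the wall confines the chain and blow-ups abort with a diagnostic", {
  cfg <- sim_config(n_beads = 6, n_steps = 4e4, n_replicas = 2,
                    equilibration_steps = 1000, tether_height = 2,
                    binding_depth = 0, seed = 5)
  res <- run_brownian(build_chain(NULL, cfg))
  # soft harmonic wall: penetration beyond ~sqrt(kT/k_wall) is not seen
  expect_gt(min(res$heights$height), -0.35)

  bad <- sim_config(n_beads = 2, n_steps = 3e5, n_replicas = 1,
                    equilibration_steps = 0, bond_stiffness = 0,
                    tether_height = 0.5, binding_depth = 0,
                    tether = FALSE, wall = FALSE, seed = 1)
  # unbonded free beads diffuse until the runaway check trips
  expect_error(run_brownian(build_chain(NULL, bad)), "blow-up")
})

test_that("without attraction a short tether never produces bound dwells", {
  cfg <- sim_config(n_beads = 15, n_steps = 1e5, n_replicas = 2,
                    equilibration_steps = 2000, binding_depth = 0, seed = 9)
  res <- run_brownian(build_chain(NULL, cfg))
  tr <- detect_events_all(res)
  expect_equal(length(tr$bound_dwells), 0L)
  expect_equal(length(tr$censored_bound), 0L)
})

test_that("event detection applies the two-threshold state machine exactly", {
  tr <- detect_events(c(3, 0.8, 0.9, 2, 3), dt = 1)
  expect_equal(tr$bound_dwells, 2)               # one bound dwell, 2 samples
  expect_equal(length(tr$unbound_dwells), 0L)    # both unbound ends censored
  expect_equal(sort(tr$censored_unbound), c(1, 2))
  expect_equal(tr$total_time, 5)

  none <- detect_events(c(3, 4, 2, 5), dt = 1)
  expect_equal(length(none$bound_dwells) + length(none$unbound_dwells), 0L)
  expect_equal(none$censored_unbound, 4)

  # single-cutoff fidelity mode: 1.2 nm is bound-side chatter no longer
  single <- detect_events(c(3, 0.8, 1.2, 0.8, 3), dt = 1,
                          bind_cutoff = 1, unbind_cutoff = 1)
  expect_equal(single$bound_dwells, c(1, 1))
  expect_equal(single$unbound_dwells, 1)
  dual <- detect_events(c(3, 0.8, 1.2, 0.8, 3), dt = 1)
  expect_equal(dual$bound_dwells, 3)

  expect_error(detect_events(numeric(0), dt = 1), "empty")
  expect_error(detect_events(c(1, 2), dt = 1, unbind_cutoff = 0.5), ">=")
})

test_that("telegraph surrogate heights reproduce the generator's own event log", {
  sim <- gen_telegraph(k_on = 0.8, k_off = 1.6, duration = 400, seed = 21)
  dt <- sim$heights$time[2] - sim$heights$time[1]
  tr <- detect_events(sim$heights, dt = dt)
  n_true <- sum(sim$events$state == "bound" & !sim$events$censored)
  # sampling discretisation can drop dwells shorter than the sampling step
  expect_gt(length(tr$bound_dwells), 0.9 * n_true)
  expect_lt(abs(length(tr$bound_dwells) - n_true), 0.1 * n_true + 3)
  # recovered mean dwells agree with the generator's bookkeeping
  expect_equal(mean(tr$bound_dwells), mean(sim$trace$bound_dwells),
               tolerance = 0.1)
})

test_that("the binding well obeys Boltzmann statistics (reweighting check)", {
  # small chain over a low tether so the end samples the well freely
  mk <- function(depth, seed) {
    cfg <- sim_config(n_beads = 5, tether_height = 2, binding_depth = depth,
                      n_steps = 3e5, n_replicas = 3,
                      equilibration_steps = 5000, seed = seed)
    run_brownian(build_chain(NULL, cfg))$heights$height
  }
  h0 <- mk(0, 31)
  h2 <- mk(2, 32)
  breaks <- seq(0, 3, by = 0.5)
  p0 <- hist(h0[h0 < 3 & h0 > 0], breaks = breaks, plot = FALSE)$density
  p2 <- hist(h2[h2 < 3 & h2 > 0], breaks = breaks, plot = FALSE)$density
  mids <- breaks[-1] - 0.25
  # reweight the well-free run by exp(-U) and renormalize
  w <- p0 * exp(-binding_potential(mids, depth = 2, range = 1))
  w <- w / sum(w * 0.5)
  p2n <- p2 / sum(p2 * 0.5)
  expect_lt(max(abs(w - p2n)), 0.12)   # coarse-bin Monte-Carlo tolerance

  # equilibrium bound fraction grows with well depth
  h4 <- mk(4, 33)
  fb <- c(mean(h0 < 1), mean(h2 < 1), mean(h4 < 1))
  expect_true(all(diff(fb) > 0))
})
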