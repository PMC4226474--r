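test_that("rate estimates are reciprocal mean dwells with sane intervals", {
  tr <- event_trace(bound_dwells = c(1, 1), unbound_dwells = c(2, 2),
                    total_time = 6)
  est <- estimate_rates(tr, n_boot = 100)
  expect_equal(est$k_on, 0.5)
  expect_equal(est$k_off, 1)
  expect_true(est$ci_on[1] <= est$k_on && est$k_on <= est$ci_on[2])
  expect_true(est$ci_off[1] <= est$k_off && est$k_off <= est$ci_off[2])

  one_sided <- event_trace(bound_dwells = 2, unbound_dwells = numeric(0),
                           censored_unbound = c(1, 1), total_time = 4)
  expect_error(estimate_rates(one_sided), "unbound")
})

test_that("rate estimator is covariant under time rescaling", {
  sim <- gen_telegraph(1, 5, duration = 500, seed = 8, emit_heights = FALSE)
  est <- estimate_rates(sim$trace, n_boot = 50)
  for (c_scale in c(0.1, 10)) {
    tr2 <- event_trace(sim$trace$bound_dwells * c_scale,
                       sim$trace$unbound_dwells * c_scale,
                       sim$trace$censored_bound * c_scale,
                       sim$trace$censored_unbound * c_scale,
                       total_time = sim$trace$total_time * c_scale)
    est2 <- estimate_rates(tr2, n_boot = 50)
    expect_equal(est2$k_on, est$k_on / c_scale)
    expect_equal(est2$k_off, est$k_off / c_scale)
  }
})

test_that("telegraph ground truth is recovered by both estimators", {
  sim <- gen_telegraph(k_on = 1, k_off = 5, duration = 4000, seed = 13,
                       emit_heights = FALSE)
  expect_gt(length(sim$trace$bound_dwells), 2000)
  est <- estimate_rates(sim$trace, n_boot = 200)
  expect_lt(abs(est$k_on - 1) / 1, 0.1)
  expect_lt(abs(est$k_off - 5) / 5, 0.1)
  # censoring-aware exponential MLE agrees closely at this event count
  mle <- estimate_rates(sim$trace, n_boot = 50, method = "exponential")
  expect_equal(mle$k_on, est$k_on, tolerance = 0.02)
  expect_equal(mle$k_off, est$k_off, tolerance = 0.02)
})

test_that("rates are scaled against the reference linker", {
  ests <- data.frame(linker = c("A", "B", "C"),
                     k_on = c(2, 1, 0.5), k_off = c(4, 2, 1))
  sc <- scale_rates(ests, reference = "A")
  expect_equal(sc$scaled_kon, c(1, 0.5, 0.25))
  expect_equal(sc$scaled_koff, c(1, 0.5, 0.25))
  expect_equal(scale_rates(ests)$scaled_kon[1], 1)   # default: first linker
  expect_error(scale_rates(ests, reference = "Z"), "not found")
})

test_that("PMF recovers a known Boltzmann density", {
  set.seed(99)
  # harmonic well at 3 nm, sd 0.5 nm -> W(z) = (z-3)^2 / (2 * 0.25) in kT
  z <- rnorm(5e4, mean = 3, sd = 0.5)
  pmf <- pmf_from_heights(z, bin_width = 0.1, bind_cutoff = 10)
  expect_equal(pmf$most_probable_bound_height, 3, tolerance = 0.15)
  sel <- abs(pmf$bin_centers - 3) < 1 & is.finite(pmf$free_energy)
  expected <- (pmf$bin_centers[sel] - 3)^2 / (2 * 0.25)
  expect_lt(max(abs(pmf$free_energy[sel] - expected)), 0.25)
  # at its own minimum the profile is flat
  expect_lt(pmf$force_at_minimum, 1)

  # uniform samples give a flat profile
  set.seed(100)
  u <- runif(5e4, 0, 5)
  flat <- pmf_from_heights(u, bind_cutoff = 5)
  rng <- range(flat$free_energy, na.rm = TRUE)
  expect_lt(diff(rng), 0.4)

  # no samples in the bound region -> force undefined and flagged
  far <- pmf_from_heights(rnorm(2e4, 8, 0.5), bind_cutoff = 1)
  expect_true(is.na(far$force_at_minimum))
  expect_true(attr(far, "bound_region_empty"))
})

test_that("subtracting the well exposes the tether tension in the PMF slope", {
  set.seed(7)
  # end height distributed as exp(-U_well - f*z): a tilted well; the total
  # PMF is flat at its minimum, the well-subtracted slope returns f (in kT/nm)
  f_true <- 1.5
  zs <- seq(0.005, 0.995, by = 0.01)
  w <- exp(-binding_potential(zs, 7, 1) - f_true * zs)
  z <- sample(zs, 5e4, replace = TRUE, prob = w) +
    runif(5e4, -0.005, 0.005)
  pmf <- pmf_from_heights(z, bind_cutoff = 1,
                          subtract_potential = function(z)
                            binding_potential(z, 7, 1),
                          temperature_kT = 1)
  expect_equal(pmf$force_at_minimum, f_true, tolerance = 0.25)
})
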