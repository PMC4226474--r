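test_that("unit counts, contour lengths and Flory radii match the packaged linker table", {
  tb <- peg_linker_table()
  expect_equal(nrow(tb), 9L)

  counts <- vapply(tb$mw, peo_unit_count, integer(1))
  expect_equal(counts, tb$n_units)

  lc <- round_half_up(vapply(tb$mw, function(m) contour_length(polymer_spec(m)),
                             numeric(1)), 1)
  expect_equal(lc, tb$contour_length_nm)

  # the shortest linker's printed coil radius does not follow the a*n^(3/5)
  # law (0.28 * 2^0.6 = 0.42); all longer linkers reproduce exactly
  rf <- round_half_up(vapply(tb$mw, function(m) flory_radius(polymer_spec(m)),
                             numeric(1)), 1)
  expect_equal(rf[-1], tb$flory_radius_nm[-1])
  expect_equal(rf[1], 0.4)
})

test_that("chain dimensions are monotone in MW with the coil inside the contour", {
  mws <- c(88, 484, 2000, 3500, 5000, 7500, 15000, 30000, 60000)
  lc <- vapply(mws, function(m) contour_length(polymer_spec(m)), numeric(1))
  rf <- vapply(mws, function(m) flory_radius(polymer_spec(m)), numeric(1))
  expect_true(all(diff(lc) > 0))
  expect_true(all(diff(rf) > 0))
  expect_true(all(rf < lc))

  # exact 3/5 scaling exponent of the closed form
  slope <- coef(lm(log(rf) ~ log(mws / 44)))[2]
  expect_equal(unname(slope), 0.6, tolerance = 1e-12)
})

test_that("single-monomer edge cases and rounding conventions hold", {
  expect_equal(peo_unit_count(44), 1L)
  expect_equal(contour_length(polymer_spec(44)), 0.28)
  expect_equal(flory_radius(polymer_spec(44)), 0.28)
  expect_equal(peo_unit_count(66), 2L)        # 1.5 rounds half up
  expect_equal(round_half_up(0.25, 1), 0.3)   # ties away from zero
  expect_error(polymer_spec(-5), "positive")
  expect_error(peo_unit_count(0), "positive")
})

test_that("entropic spring force matches the Gaussian-chain closed form", {
  # direct arithmetic oracle: f = 3 kT x / (n a^2)
  expect_equal(entropic_extension_force(4000, extension = 9, kT = 4.11),
               3 * 4.11 * 9 / ((4000 / 44) * 0.28^2))
  expect_equal(entropic_extension_force(4000, 0), 0)
  # inverse proportionality to chain length
  f1 <- entropic_extension_force(4000, 5)
  f2 <- entropic_extension_force(8000, 5)
  expect_equal(f2, f1 / 2)
  expect_error(entropic_extension_force(88, extension = 1), "contour")
})

test_that("Rouse relaxation estimate has N^2 and 1/D scaling", {
  base <- rouse_time_estimate(2, 0.84, 1)
  expect_equal(base, 0.84^2 * 4 / (3 * pi^2))   # direct arithmetic oracle
  expect_equal(rouse_time_estimate(4, 0.84, 1), 4 * base)
  expect_equal(rouse_time_estimate(2, 0.84, 2), base / 2)
  expect_error(rouse_time_estimate(1, 0.84), "at least 2")
})
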