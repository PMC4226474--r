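test_that("responses are normalized within each experiment to its own maximum", {
  tab <- data.frame(
    linker = "A",
    experiment_id = rep(c("e1", "e2"), each = 3),
    time_h = rep(1:3, 2),
    response = c(10, 20, 40, 5, 15, 30))
  norm <- normalize_response(tab)
  expect_equal(norm$response, c(0.25, 0.5, 1, 5 / 30, 0.5, 1))
  # idempotent and order-preserving
  expect_equal(normalize_response(norm)$response, norm$response)
  expect_equal(order(norm$response[1:3]), order(tab$response[1:3]))

  tab$response <- c(1, 2, 3, 0, 0, 0)
  expect_error(normalize_response(tab), "no positive response")
})

test_that("the response rate is the OLS slope with a free intercept", {
  f <- suppressWarnings(fit_rate(1:6, 0.1 * (1:6)))  # exact line: lm warns
  expect_equal(f$slope, 0.1)
  expect_equal(f$intercept, 0)
  expect_equal(suppressWarnings(fit_rate(1:5, rep(0.4, 5)))$slope, 0)
  expect_error(fit_rate(c(2, 2, 2), c(1, 2, 3)), "degenerate")
  expect_error(fit_rate(1:2, 1:2), "at least 3")
})

test_that("generated curves close the loop through the rate fit", {
  exact <- gen_response_curves(noise_sd = 0, seed = 1)
  truth <- attr(exact, "true_slopes")
  fits <- suppressWarnings(fit_rates(exact))   # perfect-fit lm warnings
  expect_equal(setNames(fits$slope, fits$linker), truth, tolerance = 1e-12)
  # table shape: 6 hourly timepoints x 3 experiments per linker
  expect_equal(nrow(exact), 6 * 3 * length(truth))
  expect_true(all(table(exact$linker) == 18))

  noisy <- gen_response_curves(noise_sd = 0.02, seed = 5)
  fits <- fit_rates(noisy)
  truth <- attr(noisy, "true_slopes")[fits$linker]
  expect_true(all(abs(fits$slope - truth) < 2 * fits$se_slope + 1e-8))

  # slope attenuation from [0,1] clipping stays below 1% at default noise,
  # checked at the shallowest default slope (most exposed to the 0 clip)
  # with enough replication that sampling error is well below the bound
  big <- gen_response_curves(c(shallow = 0.05), noise_sd = 0.02,
                             n_experiments = 2000, seed = 6)
  fit_big <- fit_rate(big$time_h, big$response)
  expect_lt(abs(fit_big$slope - 0.05) / 0.05, 0.01)
})

test_that("rate-radius association recovers sign and handles degenerate input", {
  fits <- data.frame(linker = letters[1:5], slope = c(5, 4, 3, 2, 1))
  radii <- data.frame(linker = letters[1:5], value = c(1, 2, 4, 9, 14))
  assoc <- correlate_rates(fits, radii)
  expect_equal(assoc$spearman, -1)
  expect_lt(assoc$pearson, -0.9)
  expect_equal(assoc$scaled$scaled_slope, c(1, 0.8, 0.6, 0.4, 0.2))

  const <- data.frame(linker = letters[1:5], slope = rep(2, 5))
  flagged <- correlate_rates(const, radii)
  expect_true(attr(flagged, "degenerate"))
  expect_true(is.na(flagged$spearman))

  expect_error(correlate_rates(fits, radii[1:3, ]), "no paired value")
})
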