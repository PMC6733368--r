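# Sobol sequence correctness, QMC parameter sampling, and band propagation.

test_that("Sobol points match the independent reference values", {
  # frozen oracle: scipy.stats.qmc.Sobol (unscrambled), first 8 points, d=3
  ref3 <- matrix(c(0, 0, 0, 0.5, 0.5, 0.5, 0.75, 0.25, 0.25,
                   0.25, 0.75, 0.75, 0.375, 0.375, 0.625,
                   0.875, 0.875, 0.125, 0.625, 0.125, 0.875,
                   0.125, 0.625, 0.375), 8, 3, byrow = TRUE)
  expect_equal(sobol_points(8, 3), ref3)
  # and first 16 points in d = 6
  ref6 <- matrix(c(
    0, 0, 0, 0, 0, 0, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5,
    0.75, 0.25, 0.25, 0.25, 0.75, 0.75, 0.25, 0.75, 0.75, 0.75, 0.25, 0.25,
    0.375, 0.375, 0.625, 0.875, 0.375, 0.125,
    0.875, 0.875, 0.125, 0.375, 0.875, 0.625,
    0.625, 0.125, 0.875, 0.625, 0.625, 0.875,
    0.125, 0.625, 0.375, 0.125, 0.125, 0.375,
    0.1875, 0.3125, 0.9375, 0.4375, 0.5625, 0.3125,
    0.6875, 0.8125, 0.4375, 0.9375, 0.0625, 0.8125,
    0.9375, 0.0625, 0.6875, 0.1875, 0.3125, 0.5625,
    0.4375, 0.5625, 0.1875, 0.6875, 0.8125, 0.0625,
    0.3125, 0.1875, 0.3125, 0.5625, 0.9375, 0.4375,
    0.8125, 0.6875, 0.8125, 0.0625, 0.4375, 0.9375,
    0.5625, 0.4375, 0.0625, 0.8125, 0.1875, 0.6875,
    0.0625, 0.9375, 0.5625, 0.3125, 0.6875, 0.1875), 16, 6, byrow = TRUE)
  expect_equal(sobol_points(16, 6), ref6)
  # skip reproduces a slice of the same sequence
  expect_equal(sobol_points(4, 3, skip = 4), ref3[5:8, ])
})

test_that("scrambling is a seeded measure-preserving digital shift", {
  a <- sobol_points(64, 2, scramble = TRUE, seed = 11)
  b <- sobol_points(64, 2, scramble = TRUE, seed = 11)
  c <- sobol_points(64, 2, scramble = TRUE, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_true(all(a >= 0 & a < 1))
  # a digital shift keeps every power-of-two block balanced per dimension
  expect_equal(colMeans(a), c(0.5, 0.5), tolerance = 0.02)
})

test_that("parameter sampling honours the Normal model and positivity", {
  # degenerate: zero covariance reproduces the estimate exactly
  p0 <- model_parameters(8e-3, 5)
  s0 <- sample_parameters(p0, n = 512, scramble_seed = 3)
  expect_equal(max(abs(sweep(s0$samples, 2, c(8e-3, 5)))), 0)
  # sample mean within 3 SE of the estimate for n = 1024
  cv <- matrix(c(1e-7, 0, 0, 0.25), 2)
  p <- model_parameters(8e-3, 5, covariance = cv)
  s <- sample_parameters(p, n = 1024, scramble_seed = 3)
  se <- sqrt(diag(cv) / s$n_retained)
  expect_true(all(abs(colMeans(s$samples) - c(8e-3, 5)) < 3 * se))
  expect_gte(s$n_retained, 1024)
  # mass below zero is removed and the set topped up to the minimum
  cv_wide <- matrix(c(1e-4, 0, 0, 25), 2)  # sd(theta_p) >> estimate
  pw <- model_parameters(8e-3, 5, covariance = cv_wide)
  sw <- sample_parameters(pw, n = 500, scramble_seed = 3)
  expect_gt(sw$n_removed, 0)
  expect_gte(sw$n_retained, 500)
  expect_true(all(sw$samples > 0))
  # non-PSD covariance is rejected at decomposition
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(sample_parameters(p0, covariance = bad, n = 512),
               "positive semidefinite")
})

test_that("propagation band is order-independent and brackets the nominal", {
  cv <- matrix(c(4e-8, 0, 0, 0.09), 2)
  p <- model_parameters(8e-3, 5, covariance = cv)
  ss <- sample_parameters(p, n = 512, scramble_seed = 5)
  small <- ss
  small$samples <- ss$samples[1:40, ]
  small$n_retained <- 40L
  band <- propagate_uncertainty(fx_recipe, small, fx_props, fx_equip)
  perm <- small
  set.seed(9)
  perm$samples <- small$samples[sample(40), ]
  band_perm <- propagate_uncertainty(fx_recipe, perm, fx_props, fx_equip)
  expect_equal(band_perm$lower, band$lower, tolerance = 1e-12)
  expect_equal(band_perm$upper, band$upper, tolerance = 1e-12)
  expect_true(all(band$lower <= band$nominal + 1e-9))
  expect_true(all(band$nominal <= band$upper + 1e-9))
  expect_equal(attr(band, "n_failed"), 0)
})

test_that("zero covariance collapses the band onto the nominal trace", {
  p0 <- model_parameters(8e-3, 5)
  s0 <- sample_parameters(p0, n = 500, scramble_seed = 2)
  s0$samples <- s0$samples[1:25, ]  # identical rows; keep the run short
  band <- propagate_uncertainty(fx_recipe, s0, fx_props, fx_equip)
  expect_equal(band$lower, band$nominal, tolerance = 1e-12)
  expect_equal(band$upper, band$nominal, tolerance = 1e-12)
})

test_that("without input variability the overall band is the nominal band", {
  cv <- matrix(c(4e-8, 0, 0, 0.04), 2)
  p <- model_parameters(8e-3, 5, covariance = cv)
  ob <- overall_uncertainty(fx_recipe, p, fx_sigmas,
                            scenario_config = NULL, n = 512,
                            scramble_seed = 4, equip = fx_equip)
  cons <- attr(ob, "constituents")
  expect_named(cons, "nominal")
  expect_equal(ob$lower, cons$nominal$lower)
  expect_equal(ob$upper, cons$nominal$upper)
})

test_that("band half-width at lod_max agrees with the delta method", {
  # small covariance: the response is locally linear in the parameters
  sd_p <- c(2e-4, 0.1)
  cv <- diag(sd_p^2)
  p <- model_parameters(8e-3, 5, covariance = cv)
  ss <- sample_parameters(p, n = 512, scramble_seed = 8)
  band <- propagate_uncertainty(fx_recipe, ss, fx_props, fx_equip)
  lm_at <- function(thp, the)
    attr(simulate_recipe(fx_recipe, model_parameters(thp, the), fx_props,
                         fx_equip, output_dt = 30), "lod_max")
  g <- c((lm_at(8e-3 + 1e-5, 5) - lm_at(8e-3 - 1e-5, 5)) / 2e-5,
         (lm_at(8e-3, 5.01) - lm_at(8e-3, 4.99)) / 0.02)
  delta_hw <- qnorm(0.975) * sqrt(sum((g * sd_p)^2))
  iv <- attr(band, "lod_max_interval")
  expect_equal((iv[2] - iv[1]) / 2, delta_hw, tolerance = 0.15)
})
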