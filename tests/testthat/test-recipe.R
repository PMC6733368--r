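# Recipe domain types, file round-trips, disturbances and humidity grouping.

test_that("phase and recipe invariants are enforced", {
  expect_error(phase("p", "premix", 0, 60, 0.4), "duration")
  expect_error(phase("d", "dry", 300, 60, 0.4, F_spray_set = 0.01),
               "F_spray_set")
  expect_error(phase("s", "spray", 300, 60, -0.1), ">= 0")
  ph <- list(phase("premix", "premix", 600, 60, 0.4),
             phase("s1", "spray", 600, 60, 0.4, 0.009),
             phase("d1", "dry", 600, 65, 0.4),
             phase("s2", "spray", 600, 60, 0.4, 0.009))
  expect_error(fbg_recipe(ph, 60), "contiguous")
  expect_error(fbg_recipe(ph[1:3], 60, lod_0 = 100), "lod_0")
  expect_error(fbg_recipe(ph[1:3], 60, w_s = 1), "w_s")
  expect_s3_class(fbg_recipe(ph[1:3], 60), "fbg_recipe")
})

test_that("recipe YAML round-trip reproduces every field", {
  p1 <- tempfile(fileext = ".yaml")
  p2 <- tempfile(fileext = ".yaml")
  write_recipe(fx_recipe, p1)
  r1 <- read_recipe(p1)
  write_recipe(r1, p2)
  r2 <- read_recipe(p2)
  expect_equal(r1, fx_recipe)
  expect_equal(r2, r1)
  unlink(c(p1, p2))
})

test_that("recipe reader validates schema and units", {
  p <- tempfile(fileext = ".yaml")
  writeLines(c("m_solids_0: 60", "phases:", "  - name: a", "    kind: dry",
               "    duration: 10", "    T_in_set: 60"), p)
  expect_error(read_recipe(p), "F_air_set")
  # minutes are converted on read
  writeLines(c("m_solids_0: 60", "time_unit: min", "phases:",
               "  - {name: a, kind: premix, duration: 10, T_in_set: 60,",
               "     F_air_set: 0.4}"), p)
  expect_equal(read_recipe(p)$phases[[1]]$duration, 600)
  # invariant violation inside a file: spray rate in a dry phase
  writeLines(c("m_solids_0: 60", "phases:",
               "  - {name: a, kind: dry, duration: 600, T_in_set: 60,",
               "     F_air_set: 0.4, F_spray_set: 0.01}"), p)
  expect_error(read_recipe(p), "F_spray_set")
  expect_error(read_recipe(tempfile()), "not found")
  unlink(p)
})

test_that("batch CSV round-trip preserves samples in t_min,lod_pct", {
  b <- make_batch(fx_recipe, fx_true, noise_sd = 0.05, time_jitter_sd = 10,
                  seed = 4, equip = fx_equip)
  p <- tempfile(fileext = ".csv")
  write_batch_csv(b, p)
  expect_identical(names(read.csv(p)), c("t_min", "lod_pct"))
  b2 <- read_batch_csv(p, fx_recipe, label = b$label)
  expect_equal(b2$samples, b$samples, tolerance = 1e-12)
  unlink(p)
})

test_that("apply_disturbance offsets, clamps and is additive pre-clamp", {
  sig <- parameter_std_devs(sigma_F_spray = 0.01)
  rec <- fx_recipe
  # zero magnitude: identity
  pr0 <- disturbance_profile("F_spray", 1:5, 0, "wet")
  expect_equal(apply_disturbance(rec, pr0, sig), rec)
  # +2 sigma on F_spray in subphase 3 only: 0.009 + 2*0.01 elsewhere intact
  pr <- disturbance_profile("F_spray", 3, 2, "wet")
  out <- apply_disturbance(rec, pr, sig)
  sp <- which(vapply(out$phases, `[[`, "", "kind") == "spray")
  expect_equal(out$phases[[sp[3]]]$F_spray_set, 0.009 + 0.02)
  expect_equal(out$phases[[sp[2]]]$F_spray_set, 0.009)
  expect_equal(out$phases[[sp[1]]]$T_in_set, 60)
  # dry direction drives spray rate negative -> clamped with warning
  prneg <- disturbance_profile("F_spray", 1:5, 30, "dry")
  expect_warning(out2 <- apply_disturbance(rec, prneg, sig), "clamped")
  expect_equal(out2$phases[[sp[1]]]$F_spray_set, 0)
  # additivity before clamping: a then b == summed magnitudes
  pa <- disturbance_profile("T_in", 2, 1, "wet")
  pb <- disturbance_profile("T_in", 2, 2, "wet")
  pab <- disturbance_profile("T_in", 2, 3, "wet")
  expect_equal(apply_disturbance(apply_disturbance(rec, pa, sig), pb, sig),
               apply_disturbance(rec, pab, sig))
  # unknown subphase index
  expect_error(apply_disturbance(rec, disturbance_profile("T_in", 9, 1,
                                                          "wet"), sig),
               "subphase")
})

test_that("pulsed disturbances split phases without changing totals", {
  sig <- fx_sigmas
  pulses <- data.frame(start = c(700, 1500), duration = c(300, 300))
  pr <- disturbance_profile("T_in", 1:5, 2, "dry", pulses = pulses)
  out <- apply_disturbance(fx_recipe, pr, sig)
  expect_equal(recipe_duration(out), recipe_duration(fx_recipe))
  expect_equal(sprayed_mass(out)$binder, sprayed_mass(fx_recipe)$binder)
  tin <- vapply(out$phases, `[[`, 0, "T_in_set")
  expect_true(any(tin > 60))   # dry deviation heats inside the windows
  expect_true(any(tin == 60))  # untouched outside
})

test_that("total sprayed binder is preserved by subphase timing permutation", {
  m0 <- sprayed_mass(fx_recipe)
  rec <- fx_recipe
  sp <- which(vapply(rec$phases, `[[`, "", "kind") == "spray")
  rec$phases[sp] <- rec$phases[rev(sp)]
  expect_equal(sprayed_mass(rec)$binder, m0$binder)
  expect_equal(m0$binder, fx_recipe$w_s * 0.009 * 3000)
  # rescaling spray rate at constant binder conserves the integral
  expect_equal(sprayed_mass(rescale_spray(fx_recipe, 1.25))$binder,
               m0$binder)
})

test_that("humidity grouping selects the covering group's recipe", {
  recs <- list(low = set_humidity(fx_recipe, 2),
               mid = set_humidity(fx_recipe, 5),
               high = set_humidity(fx_recipe, 8))
  expect_equal(select_recipe_by_humidity(recs, 8), recs$high)
  expect_equal(select_recipe_by_humidity(recs, 4), recs$mid)
  expect_error(select_recipe_by_humidity(recs, 0.5), "outside")
})
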