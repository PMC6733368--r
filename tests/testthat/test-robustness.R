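# Scenario enumeration, deviation scoring, design-space metrics and the
# sigma* search.

test_that("direction signs: wet wets, dry is the exact negation", {
  w <- deviation_direction_signs("wet")
  expect_equal(w[["F_spray"]], 1)
  expect_equal(w[["T_in"]], -1)
  expect_equal(w[["F_air"]], -1)
  expect_equal(deviation_direction_signs("dry"), -w)
})

test_that("deviation score is parameters times affected subphases", {
  expect_equal(deviation_score(
    scenario_spec("I", "wet", 5, c("T_in", "F_air", "F_spray"), 1:5,
                  magnitude = 2)), 15)
  expect_equal(deviation_score(
    scenario_spec("II", "dry", 5, "F_spray", 3)), 1)
  expect_equal(deviation_score(
    scenario_spec("I", "wet", 5, c("T_in", "F_air"), c(1, 3, 5),
                  magnitude = 2)), 6)
  expect_equal(deviation_score(
    scenario_spec("I", "wet", 5, "T_in", 1:2, magnitude = 0)), 0)
})

test_that("scenario enumeration matches the combinatorial oracle", {
  # independent brute-force enumerator over explicit subsets
  params <- c("T_in", "F_air", "F_spray")
  count <- 0; scores <- integer(0)
  for (k in 1:3) for (ps in utils::combn(params, k, simplify = FALSE))
    for (f in 1:5) for (fs in utils::combn(1:5, f, simplify = FALSE)) {
      count <- count + 1
      scores <- c(scores, length(ps) * length(fs))
    }
  expect_equal(count, 217)
  specs <- build_scenarios("I", fx_recipe, humidity_levels = 5,
                           directions = "wet")
  expect_length(specs, 217)
  expect_equal(sort(vapply(specs, deviation_score, 0L)), sort(scores))
  expect_equal(sort(unique(vapply(specs, deviation_score, 0L))),
               sort(unique(as.vector(outer(1:3, 1:5)))))
  expect_equal(max(vapply(specs, deviation_score, 0L)), 15)
  # both directions and three humidity levels multiply the count
  expect_length(build_scenarios("I", fx_recipe), 217 * 2 * 3)
})

test_that("sets II-IV enumerate searches as specified", {
  s2 <- build_scenarios("II", fx_recipe, humidity_levels = 5,
                        directions = "wet")
  expect_length(s2, 15)  # 3 parameters x 5 subphases
  expect_true(all(vapply(s2, function(s)
    length(s$params) == 1 && length(s$spray_subphases) == 1, TRUE)))
  s3 <- build_scenarios("III", fx_recipe, humidity_levels = 5,
                        directions = "wet")
  expect_length(s3, 7)   # parameter subsets of size 1..3
  p3 <- s3[[1]]$pulses
  expect_equal(nrow(p3), 6)                       # six pulses
  expect_true(all(p3$duration == 300))            # of five minutes
  expect_equal(sum(p3$duration), 1800)            # 30 min total
  tab <- phase_table(fx_recipe)
  expect_true(all(p3$start >= min(tab$t_start[tab$kind == "spray"])))
  expect_true(all(p3$start + p3$duration <=
                    max(tab$t_end[tab$kind == "spray"])))
  expect_equal(sort(unique(vapply(s3, deviation_score, 0L))), 1:3)
  s4 <- build_scenarios("IV", fx_recipe, humidity_levels = 5,
                        directions = "wet")
  expect_length(s4, 3)
  expect_true(all(vapply(s4, function(s)
    identical(s$spray_subphases, 1:5), TRUE)))
  # a recipe without spray subphases is rejected
  rec0 <- fbg_recipe(list(phase("premix", "premix", 600, 60, 0.4)), 60)
  expect_error(build_scenarios("I", rec0), "spray")
})

test_that("run_scenario records lod_max and the design-space flag", {
  ds <- design_space(5, 12)
  sp <- scenario_spec("I", "wet", 5, c("T_in", "F_air", "F_spray"), 1:5,
                      magnitude = 2)
  r0 <- run_scenario(fx_recipe, fx_true, sp, fx_sigmas, ds, magnitude = 0)
  expect_equal(r0$score, 0)
  nom <- attr(simulate_recipe(set_humidity(fx_recipe, 5), fx_true,
                              fx_props, fx_equip, output_dt = 30),
              "lod_max")
  expect_equal(r0$lod_max, nom, tolerance = 1e-9)
  rw <- run_scenario(fx_recipe, fx_true, sp, fx_sigmas, ds)
  expect_gte(rw$lod_max, nom)
  expect_equal(rw$score, 15)
  sp_dry <- scenario_spec("I", "dry", 5, c("T_in", "F_air", "F_spray"),
                          1:5, magnitude = 2)
  rd <- run_scenario(fx_recipe, fx_true, sp_dry, fx_sigmas, ds)
  expect_lte(rd$lod_max, nom)  # flipping direction flips the excursion
})

test_that("fraction_out_by_score counts per score", {
  res <- data.frame(score = c(6, 6, 6, 6, 1, 1),
                    in_range = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))
  f <- fraction_out_by_score(res)
  expect_equal(f$fraction_out[f$score == 6], 0.5)
  expect_equal(f$fraction_out[f$score == 1], 0)
  expect_equal(f$n[f$score == 6], 4)
  empty <- fraction_out_by_score(data.frame())
  expect_equal(nrow(empty), 0)
})

test_that("sigma* search equals the exhaustive grid oracle", {
  sp <- scenario_spec("IV", "wet", 5, "F_spray", 1:5)
  ds <- design_space(5, 11)
  grid <- 1:4
  mt <- max_tolerable_deviation(fx_recipe, fx_true, sp, fx_sigmas, ds,
                                search_range = grid)
  # independent exhaustive loop over the same grid
  lod_at <- vapply(grid, function(m)
    run_scenario(fx_recipe, fx_true, sp, fx_sigmas, ds,
                 magnitude = m)$lod_max, 0)
  in_r <- lod_at >= 5 & lod_at <= 11
  oracle <- if (any(in_r)) max(grid[in_r]) else 0
  expect_equal(mt$sigma_star, oracle)
  expect_equal(mt$grid$lod_max, lod_at, tolerance = 1e-12)
  # knife-edge design space around a point below nominal: nominal out
  mt0 <- max_tolerable_deviation(fx_recipe, fx_true, sp, fx_sigmas,
                                 design_space(0.0, 0.001),
                                 search_range = 1:2)
  expect_false(mt0$nominal_in)
  expect_true(is.na(mt0$sigma_star))
  # tolerating the whole grid returns the capped range top
  mt_cap <- max_tolerable_deviation(fx_recipe, fx_true, sp, fx_sigmas,
                                    design_space(0, 100),
                                    search_range = 1:3)
  expect_equal(mt_cap$sigma_star, 3)
  expect_true(mt_cap$capped)
})

test_that("sigma* never grows when the design space narrows", {
  sp <- scenario_spec("IV", "wet", 5, "F_spray", 1:5)
  wide <- max_tolerable_deviation(fx_recipe, fx_true, sp, fx_sigmas,
                                  design_space(5, 12),
                                  search_range = 1:6)$sigma_star
  narrow <- max_tolerable_deviation(fx_recipe, fx_true, sp, fx_sigmas,
                                    design_space(6, 10.5),
                                    search_range = 1:6)$sigma_star
  expect_lte(narrow, wide)
})
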