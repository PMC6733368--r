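# Shared fixtures: the standard pilot recipe/equipment and a cached
# noise-free trajectory, built once per test run.

fx_props <- material_properties()
fx_equip <- equipment_properties("pilot")
fx_recipe <- make_recipe("pilot", "target")
fx_true <- default_true_params()
fx_sigmas <- parameter_std_devs()

# cached nominal trajectory at the ground truth (10 s grid)
fx_traj <- simulate_recipe(fx_recipe, fx_true, fx_props, fx_equip)

# seeded random recipe around the pilot operating region, for property tests
random_recipe <- function(seed) {
  set.seed(seed)
  F_air <- runif(1, 0.3, 0.6)
  F_spray <- runif(1, 0.005, 0.013)
  T_sp <- runif(1, 50, 70)
  x_in <- runif(1, 0.001, 0.010)
  n_spray <- sample(3:5, 1)
  phases <- c(
    list(phase("premix", "premix", runif(1, 300, 900), T_sp, F_air, 0,
               x_in)),
    lapply(seq_len(n_spray), function(i)
      phase(paste0("spray-", i), "spray", runif(1, 400, 800), T_sp, F_air,
            F_spray, x_in)),
    list(phase("dry-1", "dry", runif(1, 300, 700), T_sp + runif(1, 0, 10),
               F_air, 0, x_in))
  )
  fbg_recipe(phases, m_solids_0 = runif(1, 40, 80),
             lod_0 = runif(1, 0.3, 2), w_s = runif(1, 0.05, 0.12))
}
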