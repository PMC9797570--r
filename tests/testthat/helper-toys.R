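# Shared fixtures: all built in code, frozen seeds.

# Independent linear-scan oracle for the earliest-harvest rule.
naive_harvest_week <- function(plant_week, required_gdu, cum) {
  T_ <- length(cum) - 1L
  for (h in plant_week:T_)
    if (cum[h + 1L] - cum[plant_week + 1L] >= required_gdu) return(h)
  NA_integer_
}

# Hand-built 3-population, 2-scenario instance with easily traceable
# numbers (weekly GDU 100 in scenario a, 80 in scenario b).
make_hand_instance <- function(capacity = 200) {
  pops <- data.frame(id = 1:3, early_week = c(1L, 2L, 1L),
                     late_week = c(3L, 4L, 2L),
                     required_gdu = c(250, 350, 150),
                     hq_case1 = c(100, 150, 60),
                     hq_case2 = c(150, 210, 80))
  scen <- list(gdu_scenario(rep(100, 10), "a"),
               gdu_scenario(rep(80, 10), "b"))
  gdu_instance(pops, scen, capacity = capacity)
}

# Frozen deterministic (K = 1) toy family for MILP-vs-enumeration checks.
make_det_toy <- function(seed) {
  cfg <- generator_config(
    n_populations = 4L + seed %% 3L, horizon = 18, n_scenarios = 1,
    seed = seed, window_start_range = c(1, 8), window_width_range = c(2, 4),
    required_gdu_range = c(250, 550), climate_mean = 40,
    climate_amplitude = 25, climate_noise_sd = 6)
  generate_instance(cfg, capacity_rule = "quantile")
}

# Frozen stochastic (K = 2) toy family: generator defaults scaled to T = 15
# (window widths stay "a few weeks" wide, as in the full-size data).
make_stoch_toy <- function(seed) {
  cfg <- generator_config(
    n_populations = 5L + seed %% 2L, horizon = 15, n_scenarios = 2,
    seed = seed, window_start_range = c(1, 5), window_width_range = c(3, 6),
    required_gdu_range = c(200, 450), climate_mean = 40,
    climate_amplitude = 25, climate_noise_sd = 5)
  generate_instance(cfg, capacity_rule = "quantile")
}

# A cold-climate variant: weekly GDU scaled down so far that no population
# matures inside the horizon (the cold-site analogue).
make_cold_instance <- function() {
  pops <- data.frame(id = 1:4, early_week = c(1L, 2L, 3L, 1L),
                     late_week = c(4L, 5L, 6L, 3L),
                     required_gdu = c(400, 500, 450, 420),
                     hq_case1 = c(80, 120, 90, 100),
                     hq_case2 = c(110, 160, 120, 140))
  scen <- list(gdu_scenario(rep(60, 12), "warm"),
               gdu_scenario(rep(4, 12), "cold"))
  gdu_instance(pops, scen, capacity = 150)
}
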