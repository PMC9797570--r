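test_that("generated population tables satisfy their invariants", {
  cfg <- generator_config(n_populations = 0)
  expect_equal(nrow(generate_populations(cfg)), 0)
  cfg <- generator_config(n_populations = 150, seed = 9)
  p <- generate_populations(cfg)
  expect_silent(validate_populations(p, cfg$horizon))
  expect_true(all(p$early_week >= 1 & p$early_week <= p$late_week &
                    p$late_week <= cfg$horizon))
  expect_true(all(p$hq_case2 >= p$hq_case1))
  # determinism under the seed
  expect_identical(p, generate_populations(cfg))
  expect_false(identical(p, generate_populations(
    generator_config(n_populations = 150, seed = 10))))
  expect_error(generator_config(window_width_range = c(5, 2)), "empty")
  expect_error(generator_config(case2_multiplier_range = c(0.5, 2)),
               "multiplier")
})

test_that("scenario generator shapes: noise, offset, closed form", {
  base <- generator_config(n_populations = 1, n_scenarios = 3, seed = 2,
                           climate_noise_sd = 0)
  s <- generate_scenarios(base)
  expect_length(s, 3)
  expect_true(all(vapply(s, function(x)
    identical(x$weekly, s[[1]]$weekly), logical(1))))
  cold <- generator_config(n_populations = 1, n_scenarios = 3, seed = 2,
                           climate_noise_sd = 0, site_offset = -5)
  sc <- generate_scenarios(cold)
  expect_lt(mean(sc[[1]]$weekly), mean(s[[1]]$weekly))
  # flat climate: cumulative GDU at week j is exactly j * m
  flat <- generator_config(n_populations = 1, n_scenarios = 1, seed = 2,
                           climate_amplitude = 0, climate_noise_sd = 0,
                           climate_mean = 42)
  cum <- cumulative_gdu(generate_scenarios(flat)[[1]])
  expect_equal(cum, 42 * 0:flat$horizon)
})

test_that("generate_instance sets capacity and repairs feasibility", {
  cfg <- generator_config(n_populations = 30, n_scenarios = 3, seed = 5)
  inst <- generate_instance(cfg, capacity_rule = "explicit", capacity = 7000)
  expect_equal(inst$capacity, 7000)
  expect_true(attr(feasibility_report(inst), "instance_feasible"))

  instq <- generate_instance(cfg, capacity_rule = "quantile")
  expect_gt(instq$capacity, 0)

  # a cold site forces repairs; with the repair disabled it is infeasible
  coldcfg <- generator_config(n_populations = 10, n_scenarios = 2, seed = 5,
                              horizon = 30, climate_mean = 18,
                              climate_amplitude = 10, climate_noise_sd = 2,
                              required_gdu_range = c(1200, 1600))
  rep_inst <- generate_instance(coldcfg, capacity_rule = "explicit",
                                capacity = 500)
  expect_gt(length(attr(rep_inst, "resampled")), 0)
  expect_true(attr(feasibility_report(rep_inst), "instance_feasible"))
  raw <- generate_instance(coldcfg, capacity_rule = "explicit",
                           capacity = 500, allow_infeasible = TRUE)
  expect_false(attr(feasibility_report(raw), "instance_feasible"))
})

test_that("generated instances survive the CSV readers round trip", {
  inst <- make_stoch_toy(31)
  dir <- withr::local_tempdir()
  write_populations(inst$populations, file.path(dir, "populations.csv"))
  scen <- lapply(seq_len(inst$K), function(k)
    gdu_scenario(inst$gdu[, k], colnames(inst$gdu)[k]))
  write_gdu_weekly(scen, file.path(dir, "gdu_weekly.csv"))
  p2 <- read_populations(file.path(dir, "populations.csv"),
                         horizon = inst$T)
  s2 <- read_gdu_weekly(file.path(dir, "gdu_weekly.csv"))
  inst2 <- gdu_instance(p2, s2, capacity = inst$capacity)
  expect_equal(inst2$populations, inst$populations, tolerance = 1e-12)
  expect_equal(inst2$gdu, inst$gdu, tolerance = 1e-12)
})
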