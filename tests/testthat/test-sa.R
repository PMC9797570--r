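test_that("temperature schedule is geometric", {
  cfg <- sa_config()
  expect_equal(sa_temperature(0, cfg), 30000)
  expect_equal(sa_temperature(1, cfg), 29850)
  expect_equal(sa_temperature(700, cfg), 30000 * 0.995^700)
  flat <- sa_config(alpha = 1)
  expect_equal(sa_temperature(c(0, 350, 700), flat), rep(30000, 3))
  expect_error(sa_temperature(701, cfg))
})

test_that("Metropolis acceptance has the right probabilities", {
  # improving moves: always
  set.seed(1)
  expect_true(all(replicate(20, sa_accept(100, 50, 5))))
  expect_true(all(replicate(20, sa_accept(100, 100, 5))))
  # dE = T ln 2 -> acceptance probability one half
  temp <- 37
  de <- temp * log(2)
  set.seed(2)
  acc <- mean(replicate(4000, sa_accept(100, 100 + de, temp)))
  expect_equal(acc, 0.5, tolerance = 0.04)
  # T -> 0+: essentially never accept a worse move
  set.seed(3)
  expect_false(any(replicate(200, sa_accept(100, 101, 1e-6))))
  # the literal variant always accepts worse moves (exp of a positive)
  set.seed(4)
  expect_true(all(replicate(50, sa_accept(100, 150, 10,
                                          acceptance = "literal"))))
})

test_that("initial solutions are feasible, seeded, and unique when forced", {
  inst <- make_stoch_toy(11)
  set.seed(7); s1 <- sa_initial_solution(inst)
  set.seed(7); s2 <- sa_initial_solution(inst)
  expect_identical(s1, s2)
  expect_silent(validate_schedule(s1, inst))
  expect_equal(nrow(evaluate_profile(s1, inst)$unreached), 0)
  # width-one windows -> deterministic without randomness
  pops <- data.frame(id = 1:2, early_week = c(2L, 3L), late_week = c(2L, 3L),
                     required_gdu = c(100, 150), hq_case1 = c(10, 20),
                     hq_case2 = c(12, 24))
  u <- gdu_instance(pops, list(gdu_scenario(rep(60, 8), "x")), capacity = 20)
  expect_equal(unname(sa_initial_solution(u)), c(2L, 3L))
  # infeasible instance: classed condition naming populations
  err <- tryCatch(sa_initial_solution(make_cold_instance()),
                  gduplan_infeasible = function(c) c)
  expect_s3_class(err, "gduplan_infeasible")
  expect_equal(err$offending, 1:4)
})

test_that("neighbors stay inside windows and target the right populations", {
  inst <- make_stoch_toy(12)
  set.seed(8)
  s <- sa_initial_solution(inst)
  for (rep in 1:50) {
    s2 <- sa_neighbor(s, inst, sa_config())
    expect_silent(validate_schedule(s2, inst))
    expect_equal(nrow(evaluate_profile(s2, inst)$unreached), 0)
    s <- s2
  }

  # hand-set toy: all three harvested the same week; move (a) must target
  # the smallest harvest quantities at that (tallest) week
  pops <- data.frame(id = 1:3, early_week = 3L, late_week = 7L,
                     required_gdu = 100, hq_case1 = c(500, 20, 80),
                     hq_case2 = c(600, 30, 90))
  inst3 <- gdu_instance(pops, list(gdu_scenario(rep(60, 12), "x")),
                        capacity = 300)
  s0 <- validate_schedule(c(5L, 5L, 5L), inst3)
  set.seed(9)
  nb <- sa_neighbor(s0, inst3, sa_config(moves_per_max_week = 2))
  moved <- names(s0)[s0 != nb]
  expect_true(all(moved %in% c("2", "3")))  # the two smallest HQs
  expect_equal(length(attr(nb, "moves")) >= 2, TRUE)

  # single-population instance: only that population can move (or no-op)
  p1 <- data.frame(id = 9L, early_week = 2L, late_week = 6L,
                   required_gdu = 100, hq_case1 = 10, hq_case2 = 12)
  i1 <- gdu_instance(p1, list(gdu_scenario(rep(60, 10), "x")), capacity = 10)
  set.seed(10)
  n1 <- sa_neighbor(validate_schedule(3L, i1), i1, sa_config())
  expect_true(abs(n1 - 3L) %in% c(0L, 1L, 2L))
})

test_that("annealing is seeded, monotone in best energy, and re-evaluated", {
  inst <- make_stoch_toy(13)
  cfg <- sa_config(k_max = 300, seed = 5)
  a <- sa_anneal(inst, cfg)
  b <- sa_anneal(inst, cfg)
  expect_identical(a$trace, b$trace)
  expect_identical(a$result$schedule, b$result$schedule)
  expect_true(all(diff(a$trace$best) <= 0))
  expect_equal(a$result$objective,
               objective_case1_stoch(evaluate_profile(a$result$schedule,
                                                      inst),
                                     inst$capacity))
  # k_max = 0 returns the (seeded) initial solution
  z <- sa_anneal(inst, sa_config(k_max = 0, seed = 5))
  expect_equal(nrow(z$trace), 0)
  set.seed(5)
  expect_identical(z$result$schedule, sa_initial_solution(inst))
  # SA can never beat the exact optimum
  en <- enumerate_optimum(inst, "case1_stoch", max_assignments = 5e5)
  expect_gte(a$result$objective, en$objective)
})

test_that("a unique-schedule toy is solved exactly with its exact energy", {
  pops <- data.frame(id = 1:2, early_week = c(2L, 4L), late_week = c(2L, 4L),
                     required_gdu = c(100, 120), hq_case1 = c(30, 50),
                     hq_case2 = c(40, 60))
  inst <- gdu_instance(pops, list(gdu_scenario(rep(60, 10), "x"),
                                  gdu_scenario(rep(50, 10), "y")),
                       capacity = 40)
  r <- sa_anneal(inst, sa_config(k_max = 50, seed = 1))
  expect_equal(unname(r$result$schedule), c(2L, 4L))
  expect_equal(r$result$objective,
               schedule_objective(c(2L, 4L), inst, "case1_stoch"))
})

test_that("case 2 energy minimizes envelope variation and reports capacity", {
  inst <- make_stoch_toy(14)
  inst$capacity <- NA  # capacity-sizing instance
  r <- sa_anneal(inst, sa_config(k_max = 500, seed = 2,
                                 objective = "case2_stoch"))
  expect_equal(r$result$objective,
               objective_case2_stoch(r$result$profile))
  expect_equal(r$result$capacity, max(r$result$profile$A_max))
})

test_that("SA on an infeasible instance matches the MILP diagnosis", {
  cold <- make_cold_instance()
  sa <- sa_anneal(cold, sa_config(k_max = 10, seed = 1))
  milp <- solve_stochastic_case1(cold)
  expect_equal(sa$result$status, "infeasible")
  expect_identical(sa$result$offending, milp$offending)
})
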