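test_that("case 1 model structure matches the formulation", {
  inst <- make_det_toy(1)
  m <- build_case1(inst)
  p <- inst$populations
  # t_p only inside windows; dense t_h; w; e+; e-
  expect_equal(nrow(m$vars),
               sum(p$late_week - p$early_week + 1) +
                 inst$N * inst$T + inst$T + 2 * inst$T)
  tags <- unique(m$row_tag)
  expect_setequal(tags, c("one_planting(6)", "one_harvest(8)",
                          "gdu_reach(9)", "gdu_earliest(10)",
                          "week_link(11)", "deviation(14)"))
  expect_equal(sum(m$row_tag == "deviation(14)"), inst$T)
  # LP export is writable and non-trivial
  f <- withr::local_tempfile(fileext = ".lp")
  milp_write_lp(m, f)
  expect_gt(length(readLines(f)), nrow(m$vars))
})

test_that("a width-one window forces the unique schedule", {
  pops <- data.frame(id = 1L, early_week = 3L, late_week = 3L,
                     required_gdu = 120, hq_case1 = 40, hq_case2 = 50)
  inst <- gdu_instance(pops, list(gdu_scenario(rep(50, 8), "x")),
                       capacity = 45)
  res <- solve_case1(inst)
  expect_equal(res$status, "optimal")
  expect_equal(unname(res$schedule), 3L)
  # harvest at first reach: 120 over 50/week from week 4 -> week 6
  expect_equal(unname(res$harvest_week[1, 1]), 6L)
  expect_equal(res$objective, 5)  # |45 - 40|
})

test_that("case 1 and case 2 optima equal exhaustive enumeration", {
  seeds <- c(101, 102, 103, 104)
  models1 <- list(); models2 <- list(); insts <- list()
  for (i in seq_along(seeds)) {
    insts[[i]] <- make_det_toy(seeds[i])
    models1[[i]] <- build_case1(insts[[i]])
    models2[[i]] <- build_case2(insts[[i]])
  }
  raw <- solve_milp_batch(c(models1, models2), time_limit = 120,
                          rel_gap = 1e-9)
  for (i in seq_along(seeds)) {
    r1 <- solve_model(models1[[i]], insts[[i]], raw = raw[[i]])
    en1 <- enumerate_optimum(insts[[i]], "case1_det")
    expect_equal(r1$objective, en1$objective, tolerance = 1e-9)
    # linearization identity: solver sum(e+ + e-) equals the engine value
    expect_equal(r1$solver_objective, r1$objective, tolerance = 1e-7)

    r2 <- solve_model(models2[[i]], insts[[i]],
                      raw = raw[[length(seeds) + i]])
    en2 <- enumerate_optimum(insts[[i]], "case2_det")
    expect_equal(r2$objective, en2$objective, tolerance = 1e-9)
    # z* equals the peak weekly harvest of the extracted schedule
    expect_equal(r2$capacity, max(r2$profile$A[, 1]))
  }
})

test_that("case 2 degenerate instances behave analytically", {
  # single population: z = HQ, week term = theta_w
  pops <- data.frame(id = 1L, early_week = 2L, late_week = 4L,
                     required_gdu = 100, hq_case1 = 77, hq_case2 = 90)
  inst <- gdu_instance(pops, list(gdu_scenario(rep(60, 8), "x")),
                       theta_w = 1)
  r <- solve_case2(inst, rel_gap = 1e-9)
  expect_equal(r$objective, 77 + 1)
  expect_equal(r$capacity, 77)

  # two populations forced into the same harvest week
  pops2 <- data.frame(id = 1:2, early_week = c(2L, 2L), late_week = c(2L, 2L),
                      required_gdu = c(100, 110), hq_case1 = c(30, 45),
                      hq_case2 = c(40, 60))
  inst2 <- gdu_instance(pops2, list(gdu_scenario(rep(60, 8), "x")))
  r2 <- solve_case2(inst2, rel_gap = 1e-9)
  expect_equal(r2$capacity, 75)
})

test_that("extracted harvest weeks equal the model's t_h support", {
  inst <- make_det_toy(7)
  m <- build_case1(inst)
  raw <- solve_milp_batch(list(m), time_limit = 60, rel_gap = 1e-9)[[1]]
  r <- solve_model(m, inst, raw = raw)
  x <- as.numeric(unlist(raw$x))
  for (i in seq_len(inst$N)) {
    th <- m$meta$th[[i]]
    on <- as.integer(names(th)[x[th] > 0.5])
    expect_equal(on, unname(r$harvest_week[i, 1]))
  }
})

test_that("deviations are soft: only maturity can infeasibilize", {
  # capacity far below every harvest quantity is still feasible
  pops <- data.frame(id = 1:2, early_week = 1L, late_week = 3L,
                     required_gdu = c(100, 140), hq_case1 = c(500, 700),
                     hq_case2 = c(600, 800))
  inst <- gdu_instance(pops, list(gdu_scenario(rep(60, 8), "x")),
                       capacity = 10)
  expect_equal(solve_case1(inst)$status, "optimal")
  # a population that cannot mature does infeasibilize, pre-solver
  cold <- gdu_instance(pops, list(gdu_scenario(rep(10, 8), "x")),
                       capacity = 10)
  r <- solve_case1(cold)
  expect_equal(r$status, "infeasible")
  expect_equal(r$offending, 1:2)
})

test_that("e_minus carries only the over-capacity excess at optima", {
  # at any optimum min(e+, e-) = 0 weekly, so e-_j = max(0, A_j - C) on
  # harvesting weeks and 0 elsewhere; in particular e- vanishes whenever
  # every active week fits under the capacity (claim checked, not imposed)
  for (seed in c(41, 42)) {
    inst <- make_det_toy(seed)
    m <- build_case1(inst)
    raw <- solve_milp_batch(list(m), time_limit = 60, rel_gap = 1e-9)[[1]]
    r <- solve_model(m, inst, raw = raw)
    x <- as.numeric(unlist(raw$x))
    A <- r$profile$A[, 1]
    expect_equal(x[m$meta$en], pmax(A - inst$capacity * (A > 0), 0),
                 tolerance = 1e-6)
  }
})
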