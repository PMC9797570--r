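test_that("evaluate_profile accumulates quantities and the envelope", {
  inst <- make_hand_instance()
  # plant everything as early as possible
  prof <- evaluate_profile(c(1, 2, 1), inst)
  # scenario a: 100 GDU/week -> harvest weeks 4 (g250, p1), 6 (g350, p2),
  # 3 (g150, p3); scenario b: 80/week -> 5, 7, 3
  expect_equal(prof$harvest_week[, "a"], c(`1` = 4L, `2` = 6L, `3` = 3L))
  expect_equal(prof$harvest_week[, "b"], c(`1` = 5L, `2` = 7L, `3` = 3L))
  expect_equal(unname(prof$A[4, "a"]), 100)
  expect_equal(unname(prof$A[3, "b"]), 60)
  expect_equal(nrow(prof$unreached), 0)
  # conservation per scenario
  expect_equal(colSums(prof$A), c(a = 310, b = 310))
  expect_equal(prof$A_max, apply(prof$A, 1, max))
})

test_that("single population / identical scenarios degeneracies", {
  pops <- data.frame(id = 7L, early_week = 2L, late_week = 2L,
                     required_gdu = 90, hq_case1 = 55, hq_case2 = 70)
  inst <- gdu_instance(pops, list(gdu_scenario(rep(50, 6), "x")),
                       capacity = 60)
  prof <- evaluate_profile(2L, inst)
  expect_equal(sum(prof$A > 0), 1L)
  expect_equal(max(prof$A), 55)
  inst2 <- gdu_instance(pops, list(gdu_scenario(rep(50, 6), "x"),
                                   gdu_scenario(rep(50, 6), "y")),
                        capacity = 60)
  prof2 <- evaluate_profile(2L, inst2)
  expect_equal(prof2$A_max, prof2$A[, 1])
  expect_equal(prof2$A[, 1], prof2$A[, 2])
})

test_that("conservation holds on random toys whenever all mature", {
  for (seed in c(21, 22, 23)) {
    inst <- make_stoch_toy(seed)
    set.seed(seed)
    s <- sa_initial_solution(inst)
    prof <- evaluate_profile(s, inst)
    expect_equal(nrow(prof$unreached), 0)
    expect_equal(unname(colSums(prof$A)),
                 rep(sum(active_hq(inst)), inst$K))
  }
})

test_that("unreached pairs are reported, not dropped", {
  inst <- make_cold_instance()
  prof <- evaluate_profile(c(1, 2, 3, 1), inst)
  expect_equal(sort(unique(prof$unreached$scenario)), "cold")
  expect_equal(sort(prof$unreached$id), 1:4)
  # the cold column carries no quantity at all
  expect_equal(sum(prof$A[, "cold"]), 0)
})

test_that("case 1 deterministic objective is the capacity deviation", {
  fake <- function(A) structure(list(A = matrix(A, ncol = 1), A_max = A),
                                class = "harvest_profile")
  expect_equal(objective_case1_det(fake(c(10, 8, 0)), 10), 2)
  expect_equal(objective_case1_det(fake(rep(0, 5)), 10), 0)
  expect_equal(objective_case1_det(fake(c(6900, 7100)), 7000), 200)
  expect_error(objective_case1_det(evaluate_profile(c(1, 2, 1),
                                                    make_hand_instance()),
                                   10), "single-scenario")
})

test_that("case 1 stochastic objective: active weeks vs literal", {
  fake <- function(Am) structure(list(A = cbind(Am, Am), A_max = Am),
                                 class = "harvest_profile")
  p <- fake(c(6000, 5900, 0, 0))
  expect_equal(objective_case1_stoch(p, 6000), 100)
  expect_equal(objective_case1_stoch(p, 6000, all_weeks = TRUE),
               100 + 2 * 6000)
  expect_equal(objective_case1_stoch(fake(c(7000, 7000)), 7000), 0)
})

test_that("case 2 objectives: minimax + weeks, and envelope variation", {
  fake <- function(A) structure(list(A = matrix(A, ncol = 1), A_max = A),
                                class = "harvest_profile")
  expect_equal(objective_case2_det(fake(c(5, 9, 0)), theta_w = 1), 11)
  expect_equal(objective_case2_det(fake(4), theta_w = 0), 4)
  expect_equal(objective_case2_det(fake(rep(0, 3))), 0)

  fake2 <- function(Am) structure(list(A = cbind(Am), A_max = Am),
                                  class = "harvest_profile")
  expect_equal(objective_case2_stoch(fake2(c(100, 100, 100))), 0)
  expect_equal(objective_case2_stoch(fake2(c(50, 80, 60))), 50)
  expect_equal(objective_case2_stoch(fake2(c(0, 42, 0))), 0)
  # non-negative, zero iff constant active envelope
  set.seed(5)
  for (rep in 1:20) {
    Am <- round(runif(8, 0, 3)) * runif(8, 10, 100)
    v <- objective_case2_stoch(fake2(Am))
    act <- Am[Am > 0]
    expect_gte(v, 0)
    expect_equal(v == 0, length(unique(act)) <= 1)
  }
})

test_that("more heat never delays a harvest (monotonicity)", {
  set.seed(6)
  for (rep in 1:20) {
    w <- runif(20, 0, 60)
    w2 <- w + runif(20, 0, 30)    # pointwise increase
    g <- runif(1, 50, 600); p <- sample(10, 1)
    h1 <- harvest_week(p, g, cumulative_gdu(w))
    h2 <- harvest_week(p, g, cumulative_gdu(w2))
    if (!is.na(h1)) expect_lte(h2, h1)
  }
})
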