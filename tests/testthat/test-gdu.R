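test_that("daily_gdu clamps both temperatures into [base, cap]", {
  expect_equal(daily_gdu(30, 10), 10)
  expect_equal(daily_gdu(35, 30), 20)   # both clamp to the cap
  expect_equal(daily_gdu(8, 2), 0)      # both clamp to the base
  # vectorized, always non-negative
  set.seed(1)
  tmax <- runif(200, -20, 45); tmin <- tmax - runif(200, 0, 15)
  g <- daily_gdu(tmax, tmin)
  expect_true(all(g >= 0) && all(g <= 20))
  expect_error(daily_gdu(NA, 10), "finite")
  expect_error(daily_gdu(Inf, 10), "finite")
})

test_that("week_number follows the WEEKNUM convention and keeps counting", {
  expect_equal(week_number(as.Date("2020-01-01")), 1L)
  # first Sunday on/after Jan 2 starts week 2
  expect_equal(week_number(as.Date("2020-01-05")), 2L)
  expect_equal(week_number(as.Date("2020-01-04")), 1L)  # first Saturday
  # derived by enumerating the 2020 calendar against the rule
  expect_equal(week_number(as.Date("2020-12-31")), 53L)
  # weeks continue past the year boundary within a planning horizon
  expect_equal(week_number(as.Date("2021-01-01"), planning_year = 2020), 53L)
  expect_equal(week_number(as.Date("2021-01-03"), planning_year = 2020), 54L)
  expect_error(week_number(as.Date("2019-12-31"), planning_year = 2020),
               "before Jan 1")
  # every Sunday starts a new week: enumerate a full year
  d <- seq(as.Date("2020-01-01"), as.Date("2020-12-31"), by = "day")
  w <- week_number(d)
  starts <- d[c(TRUE, diff(w) == 1L)]
  expect_true(all(format(starts[-1], "%w") == "0"))
})

test_that("aggregate_weekly bins by week and respects the horizon", {
  d <- seq(as.Date("2023-01-01"), by = "day", length.out = 7) # a Sunday
  expect_equal(aggregate_weekly(rep(10, 7), d)$weekly, 70)
  # 2020 starts on a Wednesday: week 1 holds at most 7 days (here 4)
  d20 <- seq(as.Date("2020-01-01"), as.Date("2020-12-31"), by = "day")
  s <- aggregate_weekly(rep(1, length(d20)), d20)
  expect_length(s$weekly, 53)            # 366 days -> 53 bins
  expect_equal(s$weekly[1], 4)           # Wed-Sat
  expect_equal(sum(s$weekly), 366)
  expect_error(aggregate_weekly(c(1, 2), d20[c(1, 3)]), "gaps")
  expect_error(aggregate_weekly(rep(1, 14), d20[1:14], horizon = 70),
               "refusing to pad")
  expect_length(aggregate_weekly(rep(1, length(d20)), d20,
                                 horizon = 20)$weekly, 20)
})

test_that("cumulative_gdu is a sentinel-led running sum", {
  expect_equal(cumulative_gdu(c(5, 10, 20)), c(0, 5, 15, 35))
  expect_equal(cumulative_gdu(rep(0, 5)), rep(0, 6))
  set.seed(2)
  w <- runif(70, 0, 120)
  cum <- cumulative_gdu(w)
  expect_equal(cum[length(cum)], sum(w))
  expect_true(all(diff(cum) >= 0))
  expect_error(cumulative_gdu(c(1, -1)), "non-negative")
})

test_that("harvest_week returns the minimal reach week (vs naive scan)", {
  cum <- c(0, 100, 250, 400, 600)
  expect_equal(harvest_week(1, 300, cum), 3L)
  expect_equal(harvest_week(2, 0.5, c(0, 10, 20, 30)), 3L)
  expect_true(is.na(harvest_week(1, 1e6, cumulative_gdu(runif(70, 0, 120)))))
  expect_error(harvest_week(0, 10, cum), "outside")
  expect_error(harvest_week(1, -1, cum), "positive")
  # property: minimality pair + agreement with the naive scan
  set.seed(3)
  for (rep in 1:50) {
    cum <- cumulative_gdu(runif(30, 0, 60))
    p <- sample(30, 1); g <- runif(1, 1, 900)
    h <- harvest_week(p, g, cum)
    expect_identical(h, naive_harvest_week(p, g, cum))
    if (!is.na(h)) {
      expect_gte(cum[h + 1] - cum[p + 1], g)
      expect_lt(cum[h] - cum[p + 1], g)
    }
  }
})

test_that("scenario extension wraps the same year's series", {
  s <- gdu_scenario(1:52, "y")
  e <- extend_scenario(s, 70)
  expect_length(e$weekly, 70)
  expect_equal(e$weekly[53:70], 1:18)
  expect_equal(extend_scenario(s, 40)$weekly, 1:40)
  expect_error(extend_scenario(s, 70, method = "error"), "horizon")
})
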