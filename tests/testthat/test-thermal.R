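test_that("daily degree-day contribution follows the capping rules", {
  expect_equal(daily_degree_days(30, 10), 10)
  expect_equal(daily_degree_days(8, 2), 0)      # whole day below base
  expect_equal(daily_degree_days(35, 20), 15)   # tmax capped at 30
  expect_equal(daily_degree_days(35, 20, t_ceiling = 50), 17.5)
  # cap_max_only leaves tmin untouched
  expect_equal(daily_degree_days(35, 4, capping_rule = "cap_max_only"), 7)
  expect_equal(daily_degree_days(35, 4), 10)    # tmin floored at base
  # vectorised
  expect_equal(daily_degree_days(c(30, 8), c(10, 2)), c(10, 0))
  expect_error(daily_degree_days(NaN, 5), "non-finite")
  expect_error(daily_degree_days(5, 10), "tmax < tmin")
  expect_error(daily_degree_days(30, 10, t_base = 30, t_ceiling = 30))
})

test_that("GDD accumulation sums daily contributions over the window", {
  w <- const_weather(3, tmax = 30, tmin = 10)
  expect_equal(accumulate_gdd(w, w$date[1], w$date[3]), 30)
  # single-day window
  w1 <- const_weather(1, tmax = 20, tmin = 10)
  expect_equal(accumulate_gdd(w1, w1$date[1], w1$date[1]), 5)
  # start > end is rejected
  expect_error(accumulate_gdd(w, w$date[2], w$date[1]), "start is after")
  # cold window clamps to zero
  wc <- const_weather(5, tmax = 9, tmin = 1)
  expect_equal(accumulate_gdd(wc, wc$date[1], wc$date[5]), 0)
  # gaps are an error naming the first missing date
  wg <- const_weather(5, tmax = 20, tmin = 10)[-3, ]
  expect_error(accumulate_gdd(wg, wg$date[1], as.Date("2019-01-05")),
               "2019-01-03")
})

test_that("SDD is the stress-ceiling minus growth-ceiling accumulation", {
  cfg <- thermal_config()
  # ceilings never bind differently below 30
  w <- const_weather(10, tmax = 28, tmin = 15)
  expect_equal(compute_sdd(w, w$date[1], w$date[10], cfg), 0)
  # 10 days of (35, 20): 10 * (17.5 - 15)
  w <- const_weather(10, tmax = 35, tmin = 20)
  expect_equal(compute_sdd(w, w$date[1], w$date[10], cfg), 25)
  # a 55 degC day is capped at the 50 degC stress ceiling
  w <- const_weather(1, tmax = 55, tmin = 25)
  expect_equal(compute_sdd(w, w$date[1], w$date[1], cfg), 10)
})

test_that("grow days count days with positive contribution", {
  w5 <- const_weather(5, tmax = 30, tmin = 10)
  expect_equal(count_grow_days(w5, w5$date[1], w5$date[5]), 5)
  wc <- const_weather(5, tmax = 9, tmin = 1)
  expect_equal(count_grow_days(wc, wc$date[1], wc$date[5]), 0)
  # mixed 3 warm + 2 cold days
  wm <- const_weather(5, tmax = 25, tmin = 12)
  wm$tmax[4:5] <- 8; wm$tmin[4:5] <- 1
  expect_equal(count_grow_days(wm, wm$date[1], wm$date[5]), 3)
})

test_that("thermal engine equals the brute-force day-by-day oracle", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(3:25, 1)
    w <- random_weather(n)
    rule <- sample(c("cap_max_floor_min", "cap_max_only"), 1)
    base <- runif(1, 0, 15)
    ceil <- base + runif(1, 5, 30)
    ab <- sort(sample(n, 2, replace = TRUE)); a <- ab[1]; b <- ab[2]
    orc <- oracle_window(w, w$date[a], w$date[b], base, ceil, rule)
    expect_equal(accumulate_gdd(w, w$date[a], w$date[b], base, ceil, rule),
                 orc$gdd)
    expect_equal(count_grow_days(w, w$date[a], w$date[b], base, ceil, rule),
                 orc$grow_days)
  }
})

test_that("GDD/SDD invariants hold on random weather", {
  set.seed(202)
  cfg <- thermal_config()
  for (rep in 1:100) {
    w <- random_weather(sample(5:30, 1))
    n <- nrow(w)
    # SDD non-negative
    expect_gte(compute_sdd(w, w$date[1], w$date[n], cfg), 0)
    # monotone in window extension
    g_short <- accumulate_gdd(w, w$date[1], w$date[n - 1])
    g_full <- accumulate_gdd(w, w$date[1], w$date[n])
    expect_gte(g_full, g_short)
    # raising the ceiling never decreases GDD; raising the base never
    # increases it
    expect_gte(accumulate_gdd(w, w$date[1], w$date[n], t_ceiling = 40),
               g_full)
    expect_lte(accumulate_gdd(w, w$date[1], w$date[n], t_base = 15,
                              t_ceiling = 30), g_full)
    # additivity over a partition
    k <- sample(n - 1, 1)
    expect_equal(accumulate_gdd(w, w$date[1], w$date[k]) +
                   accumulate_gdd(w, w$date[k + 1], w$date[n]), g_full)
  }
})

test_that("stage profiles are disjoint, additive, and match recomputation", {
  cfg <- thermal_config()
  # constant weather, 4-day season split 2 + 2
  w <- const_weather(10, tmax = 32, tmin = 18)
  s <- w$date[1]; f <- w$date[3]; m <- w$date[4]
  prof <- stage_thermal_profile(s, f, m, w, cfg)
  veg <- prof[prof$stage == "vegetative", ]
  rep_ <- prof[prof$stage == "reproductive", ]
  full <- prof[prof$stage == "full_season", ]
  expect_equal(veg$gdd, rep_$gdd)  # 2 identical days each
  for (col in c("gdd", "sdd", "grow_days", "age_days")) {
    expect_equal(veg[[col]] + rep_[[col]], full[[col]])
  }
  # flowering on the sowing date gives an all-zero vegetative profile
  p0 <- stage_thermal_profile(s, s, m, w, cfg)
  expect_equal(unlist(p0[p0$stage == "vegetative",
                         c("age_days", "grow_days", "gdd", "sdd")]),
               c(age_days = 0, grow_days = 0, gdd = 0, sdd = 0))
  # out-of-order phenology errors with the plot id
  expect_error(stage_thermal_profile(f, s, m, w, cfg, plot_id = "P1"), "P1")
  # random plot equals independent whole-season recomputation
  set.seed(303)
  for (rep in 1:20) {
    w <- random_weather(30)
    d <- sort(sample(30, 3))
    prof <- stage_thermal_profile(w$date[d[1]], w$date[d[2]], w$date[d[3]],
                                  w, cfg)
    full <- prof[prof$stage == "full_season", ]
    o30 <- oracle_window(w, w$date[d[1]], w$date[d[3]], 10, 30,
                         "cap_max_floor_min")
    o50 <- oracle_window(w, w$date[d[1]], w$date[d[3]], 10, 50,
                         "cap_max_floor_min")
    expect_equal(full$gdd, o30$gdd)
    expect_equal(full$sdd, o50$gdd - o30$gdd)
    expect_equal(full$grow_days, o30$grow_days)
  }
})

test_that("batch thermal profiles agree with the single-plot path", {
  trial <- small_trial(seed = 5, n_g = 8)
  prof <- thermal_profiles(trial$plots, trial$weather)
  cfg <- thermal_config()
  for (i in sample(nrow(trial$plots), 5)) {
    p <- trial$plots[i, ]
    single <- stage_thermal_profile(p$sowing_date, p$flowering_date,
                                    p$maturity_date,
                                    trial$weather[[p$location]], cfg)
    batch <- prof[prof$plot_id == p$plot_id, names(single)]
    expect_equal(as.data.frame(batch), as.data.frame(single),
                 ignore_attr = TRUE)
  }
  # profiles keep grow_days within age_days and SDD non-negative
  expect_true(all(prof$grow_days <= prof$age_days))
  expect_true(all(prof$sdd >= -1e-9))
})
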