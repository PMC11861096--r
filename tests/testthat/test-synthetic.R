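test_that("weather generation is deterministic and respects its profile", {
  prof <- location_profile("x", mean_temp = 20, amplitude = 0, peak_doy = 15,
                           diurnal_range = 10, daily_noise_sd = 0)
  w <- generate_weather(prof, "2019-01-01", 5, seed = 1)
  # no noise, no seasonality: every day identical with the stated range
  expect_equal(unique(w$tmax - w$tmin), 10)
  expect_equal(unique(w$tmax), 25)
  # identical seeds give identical series
  prof2 <- default_locations()$temperate
  expect_identical(generate_weather(prof2, "2019-06-01", 100, seed = 9),
                   generate_weather(prof2, "2019-06-01", 100, seed = 9))
})

test_that("hot profile accumulates more seasonal stress than temperate", {
  locs <- default_locations()
  wh <- generate_weather(locs$hot, "2019-04-15", 150, seed = 4)
  wt <- generate_weather(locs$temperate, "2019-06-01", 150, seed = 4)
  cfg <- thermal_config()
  sdd_h <- compute_sdd(wh, wh$date[1], wh$date[150], cfg)
  sdd_t <- compute_sdd(wt, wt$date[1], wt$date[150], cfg)
  expect_gt(sdd_h, sdd_t)
  # and more thermal time over the same number of days
  expect_gt(accumulate_gdd(wh, wh$date[1], wh$date[150]),
            accumulate_gdd(wt, wt$date[1], wt$date[150]))
})

test_that("phenology inverts the thermal accumulation", {
  w <- const_weather(30, tmax = 30, tmin = 10)  # exactly 10 GDD/day
  ph <- simulate_phenology(50, 100, w, w$date[1])
  # requirement 50 at 10/day: reached on the 5th growing day
  expect_equal(ph$flowering_date, w$date[5])
  expect_equal(ph$maturity_date, w$date[10])
  # accumulated GDD meets the requirement with overshoot below one day
  got <- accumulate_gdd(w, w$date[1], ph$flowering_date)
  expect_gte(got, 50)
  expect_lt(got - 50, 10)
  # zero requirement flowers on the sowing date
  expect_equal(simulate_phenology(0, 0, w, w$date[3])$flowering_date,
               w$date[3])
  # unreachable requirement errors
  expect_error(simulate_phenology(1e5, 2e5, w, w$date[1]), "unreachable")
  # hotter location flowers earlier for the same genotype
  locs <- default_locations()
  wh <- generate_weather(locs$hot, "2019-06-01", 300, seed = 2)
  wt <- generate_weather(locs$temperate, "2019-06-01", 300, seed = 2)
  fh <- simulate_phenology(400, 900, wh, "2019-06-01")$flowering_date
  ft <- simulate_phenology(400, 900, wt, "2019-06-01")$flowering_date
  expect_lt(fh, ft)
})

test_that("trial simulation is reproducible and design-complete", {
  t1 <- small_trial(seed = 11)
  t2 <- small_trial(seed = 11)
  expect_identical(t1$plots, t2$plots)
  expect_identical(t1$weather, t2$weather)
  # every genotype x environment x replicate combination appears exactly once
  combos <- table(t1$plots$genotype_id,
                  paste(t1$plots$location, t1$plots$tos, t1$plots$replicate))
  expect_true(all(combos == 1))
  expect_equal(nrow(t1$plots), 24 * 4 * 2)
  # phenology respects date ordering and traits respect their domains
  expect_true(all(t1$plots$sowing_date <= t1$plots$flowering_date))
  expect_true(all(t1$plots$flowering_date <= t1$plots$maturity_date))
  expect_true(all(t1$plots$yield_g >= 0))
  expect_true(all(t1$plots$hsw_g > 0))
})

test_that("a noise-free trial reproduces genotype values exactly across reps", {
  panel <- genotype_panel(n_genotypes = 6, n_desi = 1,
                          origin_counts = c(Syria = 4, India = 1,
                                            Australia = 1), seed = 3)
  resp <- response_model(yield_ge_sd = 0, yield_block_sd = 0,
                         yield_resid_sd = 0, yield_sdd_penalty = 0,
                         hsw_ge_sd = 0, hsw_block_sd = 0, hsw_resid_sd = 0,
                         hsw_sdd_penalty = 0)
  tr <- simulate_trial(panel = panel, response = resp, seed = 8)
  env <- paste(tr$plots$location, tr$plots$tos)
  for (e in unique(env)) {
    sub <- tr$plots[env == e, ]
    r1 <- sub[sub$replicate == 1, ]
    r2 <- sub[sub$replicate == 2, ]
    expect_equal(r1$yield_g, r2$yield_g)
    expect_equal(r1$hsw_g, r2$hsw_g)
  }
  # and the yield equals potential + environment effect exactly
  sub <- tr$plots[tr$plots$location == "temperate" & tr$plots$tos == 1, ]
  expect_equal(sub$yield_g[match(panel$genotype_id, sub$genotype_id)],
               panel$yield_potential, tolerance = 1e-12)
})

test_that("the default panel matches the intended composition", {
  panel <- genotype_panel(seed = 1)
  expect_equal(nrow(panel), 148)
  expect_equal(sum(panel$type == "desi"), 10)
  expect_equal(unname(table(panel$origin)[c("Syria", "India", "Australia")]),
               c(129, 10, 9), ignore_attr = TRUE)
  expect_true(all(panel$flowering_requirement <
                    panel$maturity_requirement))
  expect_true(all(panel$heat_sensitivity >= 0))
})
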