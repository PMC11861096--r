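test_that("spearman correlation matches rank-then-Pearson with t p-values", {
  # monotone pairs
  x <- c(1, 4, 9, 16, 30)
  expect_equal(spearman_test(x, x^3)$rho, 1)
  expect_equal(spearman_test(x, -sqrt(x))$rho, -1)
  expect_equal(spearman_test(x, x^3)$p_value, 0)
  # 5-point toy with a tie, checked against exhaustive mid-rank computation
  x <- c(1, 2, 2, 3, 4); y <- c(10, 8, 9, 7, 5)
  ct <- spearman_test(x, y)
  rho_hand <- cor(c(1, 2.5, 2.5, 4, 5), c(5, 3, 4, 2, 1))
  expect_equal(ct$rho, rho_hand)
  # cross-check against the standard implementation on random data with ties
  set.seed(41)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    a <- sample(1:8, n, replace = TRUE) + runif(n, 0, 0.01)
    b <- a * sample(c(-1, 1), 1) + rnorm(n, 0, 2)
    ct <- spearman_test(a, b)
    ref <- suppressWarnings(cor.test(a, b, method = "spearman",
                                     exact = FALSE))
    expect_equal(ct$rho, unname(ref$estimate))
    expect_equal(ct$p_value, ref$p.value, tolerance = 1e-9)
  }
  # invariance under strictly monotone transforms
  a <- runif(20, 1, 5); b <- rnorm(20)
  expect_equal(spearman_test(exp(a), b)$rho, spearman_test(a, b)$rho)
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
})

test_that("significance tiers cut at 0.05 and 0.001", {
  expect_equal(significance_tier(c(0.5, 0.01, 1e-5)),
               c("ns", "p<0.05", "p<0.001"))
  expect_error(significance_tier(2))
})

test_that("exponential trend fit is exact on noiseless data", {
  x <- seq(0, 500, length.out = 20)
  y <- 2 * exp(-0.01 * x)
  ft <- fit_exponential_trend(x, y)
  expect_equal(ft$a, 2)
  expect_equal(ft$b, -0.01)
  expect_equal(ft$r2, 1)
  # log-scale fit equals the closed-form simple-regression solution
  set.seed(43)
  y2 <- y * exp(rnorm(20, 0, 0.2))
  ft2 <- fit_exponential_trend(x, y2)
  b_hat <- cov(x, log(y2)) / var(x)
  expect_equal(ft2$b, b_hat)
  expect_equal(ft2$a, exp(mean(log(y2)) - b_hat * mean(x)))
  # original-scale R2 option stays in [0, 1] here and differs from log scale
  ft3 <- fit_exponential_trend(x, y2, r2_scale = "original")
  expect_true(ft3$r2 >= 0 && ft3$r2 <= 1)
  expect_error(fit_exponential_trend(x, y - 1), "positive")
  expect_error(fit_exponential_trend(rep(1, 5), exp(1:5)), "constant")
})

test_that("pure noise yields near-zero trend R2", {
  set.seed(44)
  r2 <- replicate(40, {
    x <- runif(296, 0, 1000)
    y <- exp(rnorm(296, 5, 0.3))
    fit_exponential_trend(x, y)$r2
  })
  expect_lt(mean(r2), 0.05)
})

test_that("thermal-trait correlations recover designed associations", {
  trial <- small_trial(seed = 51, n_g = 40)
  prof <- thermal_profiles(trial$plots, trial$weather)
  cc <- correlate_thermal_traits(trial$plots, prof,
                                 periods = c("vegetative", "reproductive",
                                             "full_season"))
  # stress penalty drives yield down where stress varies: the temperate
  # site's full-season SDD correlates negatively with yield
  row <- cc[cc$location == "temperate" & cc$period == "full_season" &
              cc$thermal == "sdd" & cc$trait == "yield_g", ]
  expect_lt(row$rho, 0)
  expect_equal(row$n, 80)
  # shuffling the response destroys the correlation
  set.seed(52)
  pm <- tapply(trial$plots$yield_g,
               list(trial$plots$genotype_id,
                    paste(trial$plots$location, trial$plots$tos)), mean)
  sdd <- prof$sdd[prof$stage == "full_season" & prof$location == "temperate"]
  y <- trial$plots$yield_g[trial$plots$location == "temperate"]
  rhos <- replicate(100, spearman_test(sdd, sample(y))$rho)
  expect_lt(mean(abs(rhos)), 0.1)
})

test_that("a zero-penalty scenario shows no systematic SDD-yield link", {
  trial <- small_trial(seed = 53, n_g = 40, penalty = 0)
  # also remove the confounded sowing-time yield effects so SDD carries no
  # signal at all
  resp <- response_model(yield_env = c("hot:1" = 0, "hot:2" = 0,
                                       "temperate:1" = 0, "temperate:2" = 0),
                         yield_sdd_penalty = 0)
  trial <- simulate_trial(panel = trial$panel, response = resp, seed = 53)
  prof <- thermal_profiles(trial$plots, trial$weather)
  cc <- correlate_thermal_traits(trial$plots, prof,
                                 periods = "full_season")
  rows <- cc[cc$thermal == "sdd" & cc$trait == "yield_g", ]
  expect_true(all(rows$tier != "p<0.001" | is.na(rows$rho)))
})
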