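test_that("internal weights are normalised diagnosis counts", {
  r <- rbind(reg_row(1:100, 2013.2, 2014, 0, age = 60, dep = 2),
             reg_row(101:400, 2013.7, 2014, 0, age = 70, dep = 2))
  w <- internal_weights(r, dep = 2)
  expect_equal(w$weights$weight[w$weights$age == 60], 0.25)
  expect_equal(w$weights$weight[w$weights$age == 70], 0.75)
  expect_equal(sum(w$weights$weight), 1, tolerance = 1e-12)
  # single stratum
  w1 <- internal_weights(reg_row("a", 2013.5, 2014, 0, age = 55, dep = 1), 1)
  expect_equal(w1$weights$weight, 1)
  # record order is irrelevant
  w2 <- internal_weights(r[sample(nrow(r)), ], dep = 2)
  expect_equal(w$weights, w2$weights)
  expect_error(internal_weights(r, dep = 5), "no diagnoses")
})

test_that("standardized averages are the stated weighted means", {
  res <- data.frame(age = c(60, 70), LEL = c(10, 20), PLL = c(0.5, 0.4),
                    E_star = c(20, 50))
  w <- weight_scheme(data.frame(age = c(60, 70), weight = c(1, 3)))
  avg <- standardized_average(res, w)
  expect_equal(avg$mean_LEL, 17.5)
  expect_equal(avg$mean_PLL, 0.25 * 0.5 + 0.75 * 0.4)
  # ratio-of-means alternative
  avg2 <- standardized_average(res, w, pll = "ratio_of_means")
  expect_equal(avg2$mean_PLL, 17.5 / (0.25 * 20 + 0.75 * 50))
  # constant LEL is invariant to the weights
  resc <- transform(res, LEL = 5.0)
  expect_equal(standardized_average(resc, w)$mean_LEL, 5.0)
  # stratum mismatch is an error naming the difference
  wbad <- weight_scheme(data.frame(age = c(60, 75), weight = c(1, 1)))
  expect_error(standardized_average(res, wbad), "75")
})

test_that("banded external weights average over ages inside each band", {
  res <- data.frame(age = 60:79, LEL = rep(c(10, 20), each = 10),
                    PLL = rep(c(0.5, 0.25), each = 10))
  icss_like <- weight_scheme(
    data.frame(age_lo = c(60, 70), age_hi = c(69, 79), weight = c(0.4, 0.6)))
  avg <- standardized_average(res, icss_like)
  expect_equal(avg$mean_LEL, 0.4 * 10 + 0.6 * 20)
  expect_equal(avg$mean_PLL, 0.4 * 0.5 + 0.6 * 0.25)
})

test_that("internal and pooled weights agree when age mixes are identical", {
  ages <- rep(c(58, 63, 71, 80), times = c(2, 3, 4, 1))
  r <- do.call(rbind, lapply(1:5, function(dep)
    reg_row(paste0(dep, "-", seq_along(ages)), 2013.5, 2014, 0,
            age = ages, dep = dep)))
  res <- data.frame(age = c(58, 63, 71, 80), LEL = c(12, 10, 7, 3),
                    PLL = c(0.5, 0.45, 0.35, 0.2))
  means <- vapply(1:5, function(dep)
    standardized_average(res, internal_weights(r, dep))$mean_LEL, numeric(1))
  pooled <- standardized_average(res, pooled_weights(r))$mean_LEL
  expect_equal(means, rep(pooled, 5), tolerance = 1e-9)
})

test_that("total years lost is count times mean loss", {
  # published England 2013 figures: agreement limited by the 2-dp rounding
  expect_equal(total_years_lost(2525, 12.84), 32416, tolerance = 2e-4)
  expect_equal(total_years_lost(547, 4.42), 2418, tolerance = 2e-4)
  expect_equal(total_years_lost(0, 12.8), 0)
  expect_error(total_years_lost(-1, 5), ">= 0")
})

test_that("deprivation gradients move LEL and PLL by distinct mechanisms", {
  ages <- seq(55, 90, by = 5)
  w <- lapply(1:5, function(d) data.frame(age = ages, weight = 1))

  # equal net survival, steeper background mortality with deprivation:
  # the least deprived lose more years (longer background expectancy,
  # more to lose) AND a larger share of it -- survival-weighting
  # concentrates the deprived group's remaining life where net survival
  # is still high, so with identical R the PLL cannot rise with
  # deprivation
  sc_eq <- lel_scenario(seed = 8, theta_dep = rep(0, 5),
                        dep_alpha = 2.0e-5 * exp(0.3 * (0:4)))
  std_eq <- compute_truth(sc_eq, ages = ages, dt = 0.005,
                          weights = w)$standardized
  expect_gt(std_eq$mean_LEL[std_eq$dep == 1], std_eq$mean_LEL[std_eq$dep == 5])
  expect_gt(std_eq$mean_PLL[std_eq$dep == 1], std_eq$mean_PLL[std_eq$dep == 5])

  # the observed trend reversal needs worse net survival in the deprived
  # on top of their higher background mortality: years lost still fall
  # with deprivation while the proportion of life lost rises
  sc_rev <- lel_scenario(seed = 8)
  std_rev <- compute_truth(sc_rev, ages = ages, dt = 0.005,
                           weights = w)$standardized
  expect_gt(std_rev$mean_LEL[std_rev$dep == 1],
            std_rev$mean_LEL[std_rev$dep == 5])
  expect_lt(std_rev$mean_PLL[std_rev$dep == 1],
            std_rev$mean_PLL[std_rev$dep == 5])
})
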