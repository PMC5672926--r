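test_that("scenario life tables follow the Gompertz-Makeham recipe", {
  sc <- lel_scenario(seed = 1, rho = 1)
  lt <- make_life_table(sc)
  # no drift: all calendar years identical
  expect_equal(lt$rates[, , , 1], lt$rates[, , , dim(lt$rates)[4]])
  # deprivation gradient is strict at every age/year/sex
  expect_true(all(lt$rates["M", 5, , ] > lt$rates["M", 1, , ]))
  # constant special case
  scc <- lel_scenario(seed = 1, gm_c = 0.02, dep_alpha = rep(0, 5),
                      gm_beta = 0, rho = 1, female_factor = 1)
  ltc <- make_life_table(scc)
  expect_true(all(ltc$rates == 0.02))
  # with drift, later years have lower rates
  scd <- lel_scenario(seed = 1, rho = 0.98)
  ltd <- make_life_table(scd)
  expect_true(all(ltd$rates[, , , 2] < ltd$rates[, , , 1]))
})

test_that("simulation is reproducible and respects its parameters", {
  sc <- lel_scenario(seed = 123, annual_mean = 30, dx_years = c(2010, 2013))
  r1 <- simulate_registry(sc)
  r2 <- simulate_registry(sc)
  expect_identical(r1, r2)
  expect_true(all(r1$date_exit <= sc$censor_date))
  expect_true(all(r1$age_dx >= 40 & r1$age_dx <= 95))
  expect_error(simulate_registry(lel_scenario(seed = 1, annual_mean = 0)),
               "no diagnoses")
})

test_that("with a cured fraction of 1 all-cause survival matches the life table", {
  # single cohort year, late censoring: uncensored background death times;
  # the probability integral transform S*_i(T_i) must be uniform
  sc <- lel_scenario(seed = 321, cure_fraction = 1, annual_mean = 10000,
                     dx_years = c(1998, 1998), censor_date = 2200,
                     lt_years = c(1990, 2015))
  lt <- make_life_table(sc)
  reg <- simulate_registry(sc, lt)
  expect_gt(nrow(reg), 45000)
  expect_true(all(reg$event == 1))
  u <- vapply(seq_len(nrow(reg)), function(i)
    expected_survival(lt, list(age = reg$age_dx[i], sex = reg$sex[i],
                               dep = reg$dep[i], dx_year = reg$date_dx[i]),
                      reg$date_exit[i] - reg$date_dx[i]), numeric(1))
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("a deprivation gradient in excess hazard shows up in crude survival", {
  sc <- lel_scenario(seed = 77, annual_mean = 10000,
                     dx_years = c(2005, 2005), censor_date = 2200,
                     theta_dep = 0.3 * (0:4))
  reg <- simulate_registry(sc)
  s5 <- vapply(1:5, function(dep) {
    sub <- reg[reg$dep == dep, ]
    mean(sub$date_exit - sub$date_dx > 5)
  }, numeric(1))
  n5 <- vapply(1:5, function(dep) sum(reg$dep == dep), numeric(1))
  se <- sqrt(s5 * (1 - s5) / n5)
  # monotone decreasing within binomial error
  expect_true(all(diff(s5) < 2 * (se[-1] + se[-5])))
  expect_lt(s5[5], s5[1])
})

test_that("truth tables match closed forms and the life-table integrator", {
  # constant hazards: exponential closed forms, truncated at tau
  scc <- lel_scenario(seed = 1, gm_c = 0.02, dep_alpha = rep(0, 5),
                      gm_beta = 0, rho = 1, lambda0 = 0.1, shape = 1,
                      theta_dep = rep(0, 5), theta_age = 0)
  tr <- compute_truth(scc, ages = 50)
  tau <- scc$age_cap + 21 - 50
  E_star <- (1 - exp(-0.02 * tau)) / 0.02
  E_obs <- (1 - exp(-0.12 * tau)) / 0.12
  row <- tr$by_age[1, ]
  expect_equal(row$E_star, E_star, tolerance = 1e-5)
  expect_equal(row$E_obs, E_obs, tolerance = 1e-5)
  expect_equal(row$LEL, E_star - E_obs, tolerance = 1e-5)

  # zero excess: LEL truth is 0
  sc0 <- lel_scenario(seed = 1, lambda0 = 0)
  tr0 <- compute_truth(sc0, ages = c(60, 75), dt = 0.005)
  expect_equal(tr0$by_age$LEL, rep(0, nrow(tr0$by_age)), tolerance = 1e-6)

  # independent-path agreement: trapezoid truth E* vs the exact
  # piecewise-exponential integral on the generated table
  sc <- lel_scenario(seed = 1)
  lt <- make_life_table(sc)
  tr2 <- compute_truth(sc, ages = c(55, 70, 85), table = lt)
  for (i in seq_len(nrow(tr2$by_age))) {
    r <- tr2$by_age[i, ]
    p <- patient_profile(r$age, sc$sex, r$dep, 2013.0)
    expect_equal(r$E_star,
                 expected_life_remaining(lt, p, sc$age_cap + 21 - r$age),
                 tolerance = 1e-3)
  }
})
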