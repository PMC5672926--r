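# Small simulated dataset with deprivation structure, shared in this file.
small_sim <- function() {
  memo("small_sim", {
    sc <- lel_scenario(seed = 99, annual_mean = 60,
                       dx_years = c(2003, 2013),
                       theta_dep = 0.2 * (0:4))
    lt <- make_life_table(sc)
    reg <- simulate_registry(sc, lt)
    list(sc = sc, lt = lt, pd = make_period_dataset(reg))
  })
}

test_that("design matrix has the documented layout", {
  s <- small_sim()
  fit <- relsurv_fpm(s$pd, s$lt, df_baseline = 3, df_age = 2, df_td = 2)
  K_b <- 4; K_a <- 3; K_t <- 3
  # intercept + baseline + 4 dep dummies + age + age x dep + TD terms for
  # the 4 dep dummies and the age-spline columns
  p_expect <- 1 + (K_b - 1) + 4 + (K_a - 1) + 4 * (K_a - 1) +
    (4 + K_a - 1) * (K_t - 1)
  expect_length(coef(fit), p_expect)

  # reference pattern: quintile 1 at the reference age leaves only the
  # intercept and baseline spline columns active
  Z <- build_design(fit, list(age = fit$layout$ref_age, dep = 1), t = 2.5)
  active <- which(abs(Z) > 1e-12)
  expect_true(all(grepl("^\\(Intercept\\)$|^lnt", colnames(Z)[active])))

  # at the first baseline knot the nonlinear baseline columns vanish
  t_k1 <- exp(fit$layout$baseline$knots[1])
  Z1 <- build_design(fit, list(age = fit$layout$ref_age, dep = 1), t = t_k1)
  expect_equal(unname(Z1[1, c("lnt2", "lnt3")]), c(0, 0), tolerance = 1e-12)
})

test_that("log likelihood matches hand formulas", {
  lt <- const_lt(0.02)
  layout <- lifelost:::rs_layout(rcs_spec(c(-8, 8)), NULL, ref_age = 70,
                                 use_dep = FALSE, interaction = FALSE,
                                 td = character(0), td_spec = NULL, sex = "M")
  lam <- 0.1; mu <- 0.02
  pars <- c(log(lam), 1)  # eta = ln(lam) + ln t  => constant excess hazard

  # censored-only: ell = -sum Lambda(t)
  cens <- data.frame(age_dx = c(50, 60), dep = c(1, 3), sex = "M",
                     date_dx = 2008.0, t0 = 0, t = c(2, 5), d = 0)
  expect_equal(relsurv_loglik(pars, cens, lt, layout),
               -lam * (2 + 5), tolerance = 1e-12)

  # single event at t, no truncation: ell = ln(mu + lam) - lam t
  ev <- data.frame(age_dx = 55, dep = 2, sex = "M", date_dx = 2009.0,
                   t0 = 0, t = 3, d = 1)
  expect_equal(relsurv_loglik(pars, ev, lt, layout),
               log(mu + lam) - lam * 3, tolerance = 1e-12)

  # a zero-exposure left-truncated row adds nothing
  zero <- rbind(ev, data.frame(age_dx = 70, dep = 1, sex = "M",
                               date_dx = 2009.0, t0 = 4, t = 4, d = 0))
  expect_equal(relsurv_loglik(pars, zero, lt, layout),
               relsurv_loglik(pars, ev, lt, layout), tolerance = 1e-12)

  expect_error(relsurv_loglik(c(NA, 1), ev, lt, layout), "non-finite")
})

test_that("analytic score matches central finite differences", {
  s <- small_sim()
  sub <- as.data.frame(s$pd)[1:300, ]
  lnt <- log(sub$t[sub$d == 1])
  layout <- lifelost:::rs_layout(
    rcs_spec(quantile(lnt, c(0, .5, 1), names = FALSE)),
    rcs_spec(c(50, 70, 90)), ref_age = 70, use_dep = TRUE,
    interaction = FALSE, td = "dep",
    td_spec = rcs_spec(quantile(lnt, c(0, 1), names = FALSE)), sex = "M")
  p <- length(layout$colnames)
  # coefficients on scales commensurate with the raw basis columns
  pars <- c(-1.5, 1, 0.05, 0.1, -0.1, 0.15, 0.2, 0.01, 1e-4,
            rep(0.05, 4))
  stopifnot(length(pars) == p)
  g <- attr(relsurv_loglik(pars, sub, s$lt, layout, gradient = TRUE),
            "gradient")
  h <- 1e-6
  fd <- vapply(seq_len(p), function(j) {
    e <- numeric(p); e[j] <- h
    (relsurv_loglik(pars + e, sub, s$lt, layout) -
       relsurv_loglik(pars - e, sub, s$lt, layout)) / (2 * h)
  }, numeric(1))
  expect_equal(unname(g), fd, tolerance = 1e-5)
})

test_that("estimates are invariant to row duplication and permutation", {
  s <- small_sim()
  sub <- as.data.frame(s$pd)
  args <- list(table = s$lt, df_baseline = 2, df_age = 1, td = "none",
               interaction = FALSE)
  f1 <- do.call(relsurv_fpm, c(list(sub), args))
  f2 <- do.call(relsurv_fpm, c(list(rbind(sub, sub)), args))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-5)
  set.seed(2)
  f3 <- do.call(relsurv_fpm, c(list(sub[sample(nrow(sub)), ]), args))
  expect_equal(coef(f1), coef(f3), tolerance = 1e-5)
})

test_that("closed-form predictions and extrapolation behave", {
  m <- manual_model(log(0.1), 1)
  pr <- list(age = 60, dep = 1)
  expect_equal(predict_relative_survival(m, pr, 5), exp(-0.5),
               tolerance = 1e-12)
  expect_equal(predict_excess_hazard(m, pr, c(0.5, 2, 20)), rep(0.1, 3),
               tolerance = 1e-12)
  expect_equal(predict_relative_survival(m, pr, 1e-12), 1, tolerance = 1e-9)
  expect_error(predict(m, pr, 0), "t must be > 0")
  expect_equal(tail_slope(m, pr), 1, tolerance = 1e-12)
})

test_that("fitted model recovers a constant excess hazard and extrapolates", {
  of <- oracle_fit()
  pr <- patient_profile(60, "M", 1, 2013.0)
  tt <- seq(0.1, 10, by = 0.1)
  lam_hat <- predict_excess_hazard(of$fit, pr, tt)
  # pointwise Monte-Carlo band: delta-method SE of lambda-hat(t); the
  # estimate must sit within max(5%, 3 SE) of the constant truth 0.1
  Z <- build_design(of$fit, pr, tt)
  Zp <- build_design(of$fit, pr, tt, deriv = TRUE)
  eta_p <- drop(Zp %*% coef(of$fit))
  G <- lam_hat * (Z + Zp / eta_p)  # d lambda / d theta
  se <- sqrt(rowSums((G %*% vcov(of$fit)) * G))
  expect_true(all(abs(lam_hat - 0.1) < pmax(0.005, 3 * se)))
  # both parameters of the generating model are recovered within 3 SE
  z <- (coef(of$fit) - c(log(0.1), 1)) / sqrt(diag(vcov(of$fit)))
  expect_true(all(abs(z) < 3))
  # extrapolated relative survival stays monotone in [0, 1] while the
  # fitted tail slope is positive
  fmax <- of$fit$follow_up_max
  expect_gt(tail_slope(of$fit, pr), 0)
  R <- predict_relative_survival(of$fit, pr, seq(fmax, 5 * fmax, length = 200))
  expect_true(all(diff(R) <= 1e-12) && all(R >= 0 & R <= 1))
})

test_that("underdetermined or multi-sex fits are refused", {
  s <- small_sim()
  sub <- as.data.frame(s$pd)
  tiny <- sub[sub$d == 1, ][1:10, ]
  expect_error(relsurv_fpm(tiny, s$lt), "fewer events")
  mixed <- sub; mixed$sex[1] <- "F"
  expect_error(relsurv_fpm(mixed, s$lt), "per sex")
})

test_that("JSON serialisation round-trips predictions", {
  of <- oracle_fit()
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(of$fit, f)
  m2 <- read_model_json(f)
  pr <- list(age = 55, dep = 1)
  tt <- c(0.5, 3, 12, 40)
  expect_equal(predict_relative_survival(m2, pr, tt),
               predict_relative_survival(of$fit, pr, tt), tolerance = 1e-12)
  expect_equal(coef(m2), coef(of$fit))
})

test_that("independent maximiser agrees on a proportional-hazards fit", {
  skip_if_not_installed("flexsurv")
  s <- small_sim()
  sub <- as.data.frame(s$pd)
  fit <- relsurv_fpm(sub, s$lt, df_baseline = 3, df_age = 0, td = "none",
                     interaction = FALSE)
  bh <- lifelost:::lt_rate(s$lt, sub$sex, sub$dep,
                           floor(sub$age_dx + sub$t),
                           floor(sub$date_dx + sub$t))
  sub$depf <- factor(sub$dep)
  ff <- flexsurv::flexsurvspline(
    survival::Surv(t0, t, d) ~ depf, data = sub, bhazard = bh,
    knots = fit$layout$baseline$knots[2:3],
    bknots = fit$layout$baseline$knots[c(1, 4)])
  pr <- list(age = 60, dep = 3)
  tt <- c(0.5, 1, 2, 5, 10)
  R_ours <- predict_relative_survival(fit, pr, tt)
  R_flex <- summary(ff, newdata = data.frame(depf = "3"), t = tt,
                    type = "survival", ci = FALSE, tidy = TRUE)$est
  expect_equal(R_ours, R_flex, tolerance = 5e-3)
})
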