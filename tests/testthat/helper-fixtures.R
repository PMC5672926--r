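# Shared fixtures, built lazily once per test run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# Life table with one constant rate everywhere.
const_lt <- function(rate = 0.02, years = 2000:2015, age_cap = 99) {
  memo(paste0("lt", rate, years[1], age_cap), {
    g <- expand.grid(sex = c("M", "F"), dep = 1:5, age = 0:age_cap,
                     year = years, stringsAsFactors = FALSE)
    g$rate <- rate
    life_table(g)
  })
}

# Scenario for the constant-hazard (exponential) oracle: background 0.02,
# excess 0.1, no covariate effects, ~20k patients.
oracle_scenario <- function(n_mean = 250, seed = 42) {
  lel_scenario(seed = seed, dep_alpha = rep(0, 5), gm_c = 0.02, gm_beta = 0,
               rho = 1, lambda0 = 0.1, shape = 1, theta_dep = rep(0, 5),
               theta_age = 0, annual_mean = n_mean,
               age_mean = rep(60, 5), age_sd = 8, age_range = c(40, 80))
}

# Simulated oracle data + constant-excess fit (2-knot baseline, no
# covariates), shared between model and acceptance tests.
oracle_fit <- function() {
  memo("oracle_fit", {
    sc <- oracle_scenario()
    lt <- make_life_table(sc)
    reg <- simulate_registry(sc, lt)
    pd <- make_period_dataset(reg)
    fit <- relsurv_fpm(pd, lt, df_baseline = 1, df_age = 0,
                       use_dep = FALSE, td = "none")
    list(sc = sc, lt = lt, reg = reg, pd = pd, fit = fit)
  })
}

# The default synthetic study: ~100k male lung-like patients over five
# quintiles, full model, plus independent ground truth.  Heavy; used by the
# recovery checks.
default_run <- function() {
  memo("default_run", {
    sc <- lel_scenario(seed = 20130101)
    lt <- make_life_table(sc)
    reg <- simulate_registry(sc, lt)
    pd <- make_period_dataset(reg)
    fit <- relsurv_fpm(pd, lt)
    summ <- suppressWarnings(
      summary_table(list(lung = list(M = fit)), lt, reg))
    w <- lapply(1:5, function(dep) internal_weights(reg, dep)$weights)
    truth <- compute_truth(sc, table = lt, weights = w)
    list(sc = sc, lt = lt, reg = reg, fit = fit, summ = summ, truth = truth)
  })
}

# Hand-built model with eta = log_lambda + shape * ln t, i.e. a Weibull
# excess cumulative hazard lambda * t^shape, for closed-form checks.
manual_model <- function(log_lambda, shape = 1, sex = "M") {
  layout <- lifelost:::rs_layout(rcs_spec(c(-8, 8)), NULL, ref_age = 70,
                                 use_dep = FALSE, interaction = FALSE,
                                 td = character(0), td_spec = NULL,
                                 sex = sex)
  structure(list(coefficients = stats::setNames(c(log_lambda, shape),
                                                layout$colnames),
                 vcov = NULL, layout = layout, loglik = NA_real_,
                 grad_norm = NA_real_, iterations = 0L, convergence = TRUE,
                 n = 0L, n_events = 0L, n_hazard_violations = 0L,
                 follow_up_max = Inf),
            class = "relsurv_fpm")
}

# Tiny registry data frame builder.
reg_row <- function(id, dx, exit, event, age = 60, dep = 1, sex = "M",
                    cancer = "lung") {
  data.frame(id = id, cancer = cancer, sex = sex, dep = dep, age_dx = age,
             date_dx = dx, date_exit = exit, event = event)
}
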