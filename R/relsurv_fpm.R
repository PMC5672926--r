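#' Flexible parametric relative survival model
#'
#' Fits the log cumulative excess hazard
#' \deqn{\eta(t \mid x) = s(\ln t;\gamma) + x_{dep}'\beta_{dep} +
#'   s_a(a)'\beta_{age} + (s_a(a) \otimes x_{dep})'\beta_{int} +
#'   \sum_l s_l(\ln t;\delta_l)\, x_l}
#' by maximum likelihood on a period-analysis dataset with delayed entry,
#' where \eqn{s(\cdot)} are restricted cubic splines, \eqn{x_{dep}} are
#' deprivation-quintile dummies (quintile 1 is the reference), \eqn{s_a(a)}
#' is a restricted cubic spline in age at diagnosis (centred at a reference
#' age), and the last sum carries time-dependent effects (non-proportional
#' excess hazards) for the deprivation dummies and/or the age-spline
#' columns.  The excess cumulative hazard is \eqn{\Lambda_E = e^{\eta}} and
#' the excess hazard \eqn{\lambda_E = \Lambda_E \,
#' (\partial\eta/\partial\ln t)/t}; the all-cause hazard at an event time is
#' \eqn{h^*(t) + \lambda_E(t)} with \eqn{h^*} looked up from the population
#' life table at the subject's attained age and calendar year at exit.
#'
#' Because the spline is linear in \eqn{\ln t} beyond its boundary knots,
#' predictions beyond the observed follow-up extrapolate with a Weibull-like
#' tail — the property that makes relative-survival extrapolation (and hence
#' loss-in-expectation-of-life estimation) principled.
#'
#' The log likelihood contribution of subject \eqn{i} with entry
#' \eqn{t_{0i}}, exit \eqn{t_i} and death indicator \eqn{d_i} is
#' \deqn{d_i \ln(h^*_i + \lambda_E(t_i)) - \Lambda_E(t_i) +
#'   \Lambda_E(t_{0i}),}
#' expected-hazard terms without parameters being dropped.  Where the total
#' hazard argument of the log falls below a floor of 1e-10 it is replaced by
#' a C2-smooth quadratic surrogate so the likelihood stays differentiable;
#' any event-time violations at the optimum are counted and reported.
#'
#' Optimisation is two-stage and deterministic: a proportional-effects model
#' is fitted first from an exponential-equivalent closed-form start
#' (log event rate per person-year, unit slope in \eqn{\ln t}), then the
#' full model is warm-started from it with time-dependent coefficients at
#' zero.  Columns are internally rescaled to unit standard deviation for
#' optimiser conditioning; reported coefficients are on the raw basis scale,
#' so predictions are invariant to the rescaling.
#'
#' @param data a [make_period_dataset()] result (or data frame with columns
#'   `age_dx`, `dep`, `sex`, `date_dx`, `t0`, `t`, `d`), single sex.
#' @param table a [life_table()] supplying expected hazards.
#' @param df_baseline degrees of freedom (basis columns) of the baseline
#'   log-time spline; `df_baseline = 1` is a Weibull-type linear baseline.
#' @param df_age df of the age spline; 0 omits the age effect.
#' @param df_td df of the time-dependent effect splines; ignored when
#'   `td = "none"`.
#' @param use_dep include deprivation dummies?
#' @param interaction include age-spline x deprivation interaction
#'   (proportional)?
#' @param td which covariates get time-dependent effects: any of
#'   `"dep"`, `"age"`, or `"none"`.
#' @param knots optional list overriding data-driven knots: elements
#'   `baseline`, `age`, `td` (numeric knot vectors; baseline/td on log
#'   time).
#' @param ref_age centre of the age basis (defaults to the mean age at
#'   diagnosis of the events).
#' @param control list: `iter.max`, `eval.max`, `rel.tol` passed to the
#'   quasi-Newton optimiser.
#' @param force return the model even if convergence checks fail.
#' @return an object of class `relsurv_fpm` with components `coefficients`,
#'   `vcov`, `layout` (knots, column order, reference age, sex), `loglik`,
#'   `grad_norm`, `iterations`, `convergence`, `n`, `n_events`,
#'   `n_hazard_violations`, and `follow_up_max`.
#' @seealso [predict.relsurv_fpm()], [predict_relative_survival()],
#'   [loss_in_expectation()]
#' @export
relsurv_fpm <- function(data, table,
                        df_baseline = 5, df_age = 3, df_td = 3,
                        use_dep = TRUE, interaction = use_dep && df_age > 0,
                        td = c("dep", "age"), knots = NULL,
                        ref_age = NULL, control = list(), force = FALSE) {
  stopifnot(inherits(table, "life_table"))
  need <- c("age_dx", "dep", "sex", "date_dx", "t0", "t", "d")
  if (!all(need %in% names(data)))
    stop("data needs columns: ", paste(need, collapse = ", "),
         " (run make_period_dataset first)")
  x <- as.data.frame(data)
  if (length(unique(x$sex)) != 1L)
    stop("fit one model per sex: data contains multiple sexes")
  if (any(x$t <= 0) || any(x$t0 < 0) || any(x$t <= x$t0))
    stop("need t > t0 >= 0 for every row")
  if (df_baseline < 1) stop("df_baseline must be >= 1")
  td <- match.arg(td, c("dep", "age", "none"), several.ok = TRUE)
  if ("none" %in% td) td <- character(0)
  if (!use_dep) {
    td <- setdiff(td, "dep")
    interaction <- FALSE
  }
  if (df_age == 0) {
    td <- setdiff(td, "age")
    interaction <- FALSE
  }
  ctl <- modifyList(list(iter.max = 500L, eval.max = 1000L, rel.tol = 1e-10),
                    control)

  lnt <- log(x$t)
  ev <- x$d == 1
  n_events <- sum(ev)

  # --- knots ------------------------------------------------------------
  kb <- if (!is.null(knots$baseline)) knots$baseline else
    knots_from_data(lnt[ev], df_baseline)
  baseline <- rcs_spec(kb)
  age_spec <- NULL
  if (df_age > 0) {
    ka <- if (!is.null(knots$age)) knots$age else
      knots_from_data(x$age_dx, df_age, boundary_probs = c(0.02, 0.98))
    age_spec <- rcs_spec(ka)
  }
  td_spec <- NULL
  if (length(td) > 0) {
    kt <- if (!is.null(knots$td)) knots$td else
      knots_from_data(lnt[ev], df_td)
    td_spec <- rcs_spec(kt)
  }
  if (is.null(ref_age))
    ref_age <- if (n_events > 0) mean(x$age_dx[ev]) else mean(x$age_dx)

  layout <- rs_layout(baseline, age_spec, ref_age, use_dep, interaction,
                      td, td_spec, sex = x$sex[1])
  p <- length(layout$colnames)
  if (n_events <= p)
    stop(sprintf("fewer events (%d) than parameters (%d)", n_events, p))

  # --- design matrices (fixed for the whole optimisation) ---------------
  Z <- rs_design(layout, x$age_dx, x$dep, lnt)
  Zp <- rs_design(layout, x$age_dx, x$dep, lnt, deriv = TRUE)
  i0 <- which(x$t0 > 0)
  Z0 <- rs_design(layout, x$age_dx[i0], x$dep[i0], log(x$t0[i0]))
  hstar <- lt_rate(table, x$sex, x$dep, floor(x$age_dx + x$t),
                   floor(x$date_dx + x$t))

  scl <- apply(Z, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  scl[1] <- 1  # intercept
  Zs <- Z %*% diag(1 / scl, p)
  Zps <- Zp %*% diag(1 / scl, p)
  Z0s <- Z0 %*% diag(1 / scl, p)

  env <- list(Zs = Zs, Zps = Zps, Z0s = Z0s, d = as.numeric(x$d),
              t = x$t, hstar = hstar)

  # --- deterministic initialisation (exponential-equivalent start) ------
  theta0 <- numeric(p)
  names(theta0) <- layout$colnames
  pt <- sum(x$t - x$t0)
  theta0[1] <- log(max(n_events, 1) / pt)
  theta0[2] <- 1 * scl[2]  # unit slope in ln t, on the scaled column

  is_td <- grepl("^td:", layout$colnames)
  obj <- function(th) rs_negll(th, env)
  gr <- function(th) rs_negll_grad(th, env)

  # stage 1: proportional model
  free1 <- which(!is_td)
  fit1 <- stats::nlminb(theta0[free1],
                        function(th) {
                          full <- theta0; full[free1] <- th; obj(full)
                        },
                        function(th) {
                          full <- theta0; full[free1] <- th; gr(full)[free1]
                        },
                        control = list(iter.max = ctl$iter.max,
                                       eval.max = ctl$eval.max,
                                       rel.tol = ctl$rel.tol))
  theta1 <- theta0
  theta1[free1] <- fit1$par

  # stage 2: full model (identical to stage 1 when there are no TD terms)
  if (any(is_td)) {
    fit2 <- stats::nlminb(theta1, obj, gr,
                          control = list(iter.max = ctl$iter.max,
                                         eval.max = ctl$eval.max,
                                         rel.tol = ctl$rel.tol))
  } else fit2 <- fit1
  theta_s <- if (any(is_td)) fit2$par else theta1
  g <- gr(theta_s)
  grad_norm <- max(abs(g))
  ll <- -obj(theta_s)
  converged <- fit2$convergence == 0 || grad_norm < 1e-3 * (1 + abs(ll))
  if (!converged && !force)
    stop(sprintf(paste0("relsurv_fpm did not converge (code %d, %s; ",
                        "max|grad| = %.3g, loglik = %.6g); rerun with ",
                        "force = TRUE to inspect"),
                 fit2$convergence, fit2$message, grad_norm, ll))

  H <- stats::optimHess(theta_s, obj, gr)
  vc_s <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  Minv <- diag(1 / scl, p)
  coefficients <- drop(Minv %*% theta_s)
  names(coefficients) <- layout$colnames
  vc <- Minv %*% vc_s %*% Minv
  dimnames(vc) <- list(layout$colnames, layout$colnames)

  # count residual total-hazard violations at event times at the optimum
  eta <- drop(Zs %*% theta_s); etap <- drop(Zps %*% theta_s)
  lam <- exp(eta) * etap / x$t
  n_viol <- sum(x$d == 1 & (hstar + lam) <= 1e-10)

  structure(list(coefficients = coefficients, vcov = vc, layout = layout,
                 loglik = ll, grad_norm = grad_norm,
                 iterations = fit2$iterations,
                 convergence = converged,
                 n = nrow(x), n_events = n_events,
                 n_hazard_violations = n_viol,
                 follow_up_max = max(x$t),
                 call = match.call()),
            class = "relsurv_fpm")
}

# Covariate layout: fixed, documented column order.
rs_layout <- function(baseline, age_spec, ref_age, use_dep, interaction,
                      td, td_spec, sex) {
  nb <- length(baseline$knots) - 1L
  cn <- c("(Intercept)", paste0("lnt", seq_len(nb)))
  if (use_dep) cn <- c(cn, paste0("dep", 2:5))
  na <- 0L
  if (!is.null(age_spec)) {
    na <- length(age_spec$knots) - 1L
    cn <- c(cn, paste0("age", seq_len(na)))
  }
  if (interaction)
    cn <- c(cn, as.vector(outer(seq_len(na), 2:5,
                                function(m, j) paste0("dep", j, ":age", m))))
  td_cov <- character(0)
  if ("dep" %in% td) td_cov <- c(td_cov, paste0("dep", 2:5))
  if ("age" %in% td) td_cov <- c(td_cov, paste0("age", seq_len(na)))
  if (length(td_cov) > 0) {
    nt <- length(td_spec$knots) - 1L
    cn <- c(cn, as.vector(vapply(td_cov, function(v)
      paste0("td:", v, ":lnt", seq_len(nt)), character(nt))))
  }
  list(baseline = baseline, age_spec = age_spec, ref_age = ref_age,
       use_dep = use_dep, interaction = interaction,
       td_cov = td_cov, td_spec = td_spec, sex = sex, colnames = cn)
}

# Design matrix for eta (deriv = FALSE) or d eta / d ln t (deriv = TRUE).
rs_design <- function(layout, age, dep, lnt, deriv = FALSE) {
  n <- max(length(age), length(dep), length(lnt))
  if (n == 0L)
    return(matrix(0, 0L, length(layout$colnames),
                  dimnames = list(NULL, layout$colnames)))
  age <- rep_len(age, n); dep <- rep_len(dep, n); lnt <- rep_len(lnt, n)
  B <- if (deriv) rcs_deriv(lnt, layout$baseline) else
    rcs_basis(lnt, layout$baseline)
  cols <- list(if (deriv) rep(0, n) else rep(1, n), B)
  D <- NULL
  if (layout$use_dep) {
    D <- sapply(2:5, function(j) as.numeric(dep == j))
    if (n == 1L) D <- matrix(D, 1L)
    cols <- c(cols, list(if (deriv) matrix(0, n, 4L) else D))
  }
  A <- NULL
  if (!is.null(layout$age_spec)) {
    A <- rcs_basis(age, layout$age_spec) -
      matrix(rcs_basis(layout$ref_age, layout$age_spec),
             n, length(layout$age_spec$knots) - 1L, byrow = TRUE)
    cols <- c(cols, list(if (deriv) 0 * A else A))
  }
  if (layout$interaction) {
    IX <- do.call(cbind, lapply(2:5, function(j) A * as.numeric(dep == j)))
    cols <- c(cols, list(if (deriv) 0 * IX else IX))
  }
  if (length(layout$td_cov) > 0) {
    Ct <- if (deriv) rcs_deriv(lnt, layout$td_spec) else
      rcs_basis(lnt, layout$td_spec)
    for (v in layout$td_cov) {
      xv <- if (grepl("^dep", v)) as.numeric(dep == as.integer(sub("dep", "", v)))
            else A[, as.integer(sub("age", "", v))]
      cols <- c(cols, list(Ct * xv))
    }
  }
  Z <- do.call(cbind, cols)
  colnames(Z) <- layout$colnames
  Z
}

# C2-smoothed log below the floor eps, so the likelihood stays
# differentiable when the fitted total hazard dips to (or below) zero.
ls_eps <- 1e-10
lsafe <- function(u) {
  ifelse(u >= ls_eps, log(pmax(u, ls_eps)),
         log(ls_eps) + (u - ls_eps) / ls_eps - (u - ls_eps)^2 / (2 * ls_eps^2))
}
lsafe_d <- function(u) {
  ifelse(u >= ls_eps, 1 / pmax(u, ls_eps),
         1 / ls_eps - (u - ls_eps) / ls_eps^2)
}

rs_negll <- function(theta, env) {
  if (any(!is.finite(theta))) stop("non-finite parameters")
  eta <- pmin(drop(env$Zs %*% theta), 300)
  etap <- drop(env$Zps %*% theta)
  Lam <- exp(eta)
  lam <- Lam * etap / env$t
  u <- env$hstar + lam
  ll <- sum(env$d * lsafe(u)) - sum(Lam)
  if (nrow(env$Z0s) > 0)
    ll <- ll + sum(exp(pmin(drop(env$Z0s %*% theta), 300)))
  -ll
}

rs_negll_grad <- function(theta, env) {
  eta <- pmin(drop(env$Zs %*% theta), 300)
  etap <- drop(env$Zps %*% theta)
  Lam <- exp(eta)
  lam <- Lam * etap / env$t
  u <- env$hstar + lam
  w <- env$d * lsafe_d(u)
  g <- crossprod(env$Zs, w * lam - Lam) + crossprod(env$Zps, w * Lam / env$t)
  if (nrow(env$Z0s) > 0) {
    Lam0 <- exp(pmin(drop(env$Z0s %*% theta), 300))
    g <- g + crossprod(env$Z0s, Lam0)
  }
  -drop(g)
}

#' Log likelihood of a relative survival model at given parameters
#'
#' Evaluates the period-analysis (delayed entry) relative-survival log
#' likelihood \eqn{\sum_i d_i \ln(h^*_i + \lambda_E(t_i)) - \Lambda_E(t_i)
#' + \Lambda_E(t_{0i})} for an explicit parameter vector, using the same
#' code path as the fitter.  Mainly useful for diagnostics and for checking
#' gradients.
#'
#' @param params numeric parameter vector in the layout's column order.
#' @param data a period dataset (see [relsurv_fpm()]).
#' @param table a [life_table()].
#' @param layout a model layout, e.g. `fitted$layout`.
#' @param gradient if `TRUE`, attach the analytic score vector as attribute
#'   `"gradient"`.
#' @return the scalar log likelihood.
#' @export
relsurv_loglik <- function(params, data, table, layout, gradient = FALSE) {
  x <- as.data.frame(data)
  if (any(!is.finite(params))) stop("non-finite parameters")
  lnt <- log(x$t)
  i0 <- which(x$t0 > 0)
  env <- list(
    Zs = rs_design(layout, x$age_dx, x$dep, lnt),
    Zps = rs_design(layout, x$age_dx, x$dep, lnt, deriv = TRUE),
    Z0s = rs_design(layout, x$age_dx[i0], x$dep[i0], log(x$t0[i0])),
    d = as.numeric(x$d), t = x$t,
    hstar = lt_rate(table, x$sex, x$dep, floor(x$age_dx + x$t),
                    floor(x$date_dx + x$t)))
  ll <- -rs_negll(params, env)
  if (gradient) attr(ll, "gradient") <- -rs_negll_grad(params, env)
  ll
}

#' Design row(s) for a covariate pattern
#'
#' Assembles the model's covariate row for a profile at given times, in the
#' fixed column order stored in the fitted model.  Ages outside the age
#' spline's boundary knots trigger an extrapolation warning (linear tail),
#' not an error.
#'
#' @param model a fitted [relsurv_fpm()].
#' @param profile a [patient_profile()] or list with `age`, `dep`.
#' @param t times since diagnosis (> 0), vectorised.
#' @param deriv return the derivative design (w.r.t. log time) instead.
#' @return numeric matrix with `length(t)` rows.
#' @export
build_design <- function(model, profile, t, deriv = FALSE) {
  stopifnot(inherits(model, "relsurv_fpm"))
  if (any(t <= 0)) stop("t must be > 0")
  lay <- model$layout
  if (!is.null(lay$age_spec)) {
    kb <- range(lay$age_spec$knots)
    if (profile$age < kb[1] || profile$age > kb[2])
      warning("age ", profile$age,
              " is outside the age-spline boundary knots; ",
              "predictions use the linear tail")
  }
  rs_design(lay, profile$age, profile$dep, log(t), deriv = deriv)
}

#' Predict from a fitted relative survival model
#'
#' @param object a fitted [relsurv_fpm()].
#' @param profile a [patient_profile()] or list with `age` and `dep`.
#' @param t times since diagnosis (> 0), vectorised.
#' @param type `"relsurv"` for \eqn{R(t|x) = \exp(-e^{\eta})},
#'   `"excess_hazard"` for \eqn{\lambda_E(t|x)}, `"cumhaz"` for
#'   \eqn{\Lambda_E}, `"log_cumhaz"` for \eqn{\eta} itself.
#' @param ... unused.
#' @return numeric vector along `t`.
#' @export
predict.relsurv_fpm <- function(object, profile, t,
                                type = c("relsurv", "excess_hazard",
                                         "cumhaz", "log_cumhaz"), ...) {
  type <- match.arg(type)
  if (any(t <= 0)) stop("t must be > 0")
  Z <- build_design(object, profile, t)
  eta <- drop(Z %*% object$coefficients)
  switch(type,
         log_cumhaz = eta,
         cumhaz = exp(eta),
         relsurv = exp(-exp(eta)),
         excess_hazard = {
           Zp <- build_design(object, profile, t, deriv = TRUE)
           exp(eta) * drop(Zp %*% object$coefficients) / t
         })
}

#' @rdname predict.relsurv_fpm
#' @param model a fitted [relsurv_fpm()].
#' @export
predict_relative_survival <- function(model, profile, t)
  predict(model, profile, t, type = "relsurv")

#' @rdname predict.relsurv_fpm
#' @export
predict_excess_hazard <- function(model, profile, t)
  predict(model, profile, t, type = "excess_hazard")

#' Slope of the extrapolation tail for a covariate pattern
#'
#' The fitted \eqn{\partial\eta/\partial\ln t} beyond all spline boundary
#' knots, which is constant there.  Relative survival keeps decreasing
#' under extrapolation exactly when this slope is positive; it is surfaced
#' in [summary.relsurv_fpm()] and [age_profile()] so degenerate tails are
#' visible rather than silent.
#'
#' @inheritParams build_design
#' @return the constant tail slope (scalar).
#' @export
tail_slope <- function(model, profile) {
  lay <- model$layout
  kmax <- max(lay$baseline$knots,
              if (!is.null(lay$td_spec)) lay$td_spec$knots else -Inf)
  Zp <- suppressWarnings(build_design(model, profile, exp(kmax + 1),
                                      deriv = TRUE))
  drop(Zp %*% model$coefficients)
}

#' @export
print.relsurv_fpm <- function(x, ...) {
  cat("Flexible parametric relative survival model (log cumulative excess hazard)\n")
  cat("  sex:", x$layout$sex, "  n =", x$n, "  events =", x$n_events, "\n")
  cat("  baseline df:", length(x$layout$baseline$knots) - 1L,
      " age df:", if (is.null(x$layout$age_spec)) 0 else
        length(x$layout$age_spec$knots) - 1L,
      " TD effects:", if (length(x$layout$td_cov)) length(x$layout$td_cov)
      else "none", "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      " max|grad|:", format(x$grad_norm, digits = 3),
      " converged:", x$convergence, "\n")
  invisible(x)
}

#' @export
summary.relsurv_fpm <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               z = object$coefficients / se)
  slopes <- vapply(1:5, function(dep)
    tail_slope(object, list(age = object$layout$ref_age, dep = dep)),
    numeric(1))
  out <- list(coefficients = tab, loglik = object$loglik,
              n = object$n, n_events = object$n_events,
              n_hazard_violations = object$n_hazard_violations,
              tail_slopes = stats::setNames(slopes, paste0("dep", 1:5)),
              layout = object$layout, convergence = object$convergence)
  class(out) <- "summary.relsurv_fpm"
  out
}

#' @export
print.summary.relsurv_fpm <- function(x, ...) {
  cat("Flexible parametric relative survival model\n")
  cat("n =", x$n, " events =", x$n_events,
      " log-likelihood =", format(x$loglik, digits = 8), "\n")
  if (x$n_hazard_violations > 0)
    cat("NOTE:", x$n_hazard_violations,
        "event times with non-positive fitted total hazard\n")
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat("\nExtrapolation tail slope of eta in ln t (at reference age):\n")
  print(round(x$tail_slopes, 4))
  invisible(x)
}

#' @export
coef.relsurv_fpm <- function(object, ...) object$coefficients

#' @export
vcov.relsurv_fpm <- function(object, ...) object$vcov

#' @export
logLik.relsurv_fpm <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}
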