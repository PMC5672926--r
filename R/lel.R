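# Cached Gauss-Legendre nodes/weights on [0, 1].
gl_cache <- new.env(parent = emptyenv())
gl_rule <- function(order) {
  key <- as.character(order)
  if (is.null(gl_cache[[key]])) {
    r <- pracma::gaussLegendre(order, 0, 1)
    gl_cache[[key]] <- list(x = r$x, w = r$w)
  }
  gl_cache[[key]]
}

#' Life expectancy of a cancer patient
#'
#' \eqn{E_{obs} = \int_0^\tau S^*(t) R(t|x)\,dt}: the expected survival from
#' the population life table times the model's (extrapolated) relative
#' survival.  The integral uses fixed-order Gauss-Legendre quadrature
#' inside every piecewise-constant segment of \eqn{S^*} (segments break at
#' integer attained ages and calendar years), so the life-table factor
#' contributes no segment-crossing error and the only approximation is the
#' polynomial quadrature of the smooth factor \eqn{R}.
#'
#' @param model a fitted [relsurv_fpm()].
#' @param table a [life_table()].
#' @param profile a [patient_profile()].
#' @param tau integration horizon in years; default runs to attained age
#'   `age_cap + 21`, by which point \eqn{S^*} is effectively zero.
#' @param gl_order Gauss-Legendre order per segment.
#' @return life expectancy in years.
#' @export
observed_life_expectancy <- function(model, table, profile, tau = NULL,
                                     gl_order = 15) {
  profile <- as_profile(profile)
  if (is.null(tau)) tau <- default_tau(table, profile)
  if (tau <= 0) stop("tau must be > 0")
  path <- lt_path(table, profile, tau)
  rule <- gl_rule(gl_order)
  dl <- path$end - path$start
  # all nodes at once: segments x order
  tt <- rep(path$start, each = gl_order) +
    rep(dl, each = gl_order) * rep(rule$x, length(dl))
  ww <- rep(dl, each = gl_order) * rep(rule$w, length(dl))
  Sstar <- rep(path$S_start, each = gl_order) *
    exp(-rep(path$rate, each = gl_order) *
          (tt - rep(path$start, each = gl_order)))
  R <- predict(model, profile, tt, type = "relsurv")
  sum(ww * Sstar * R)
}

#' Loss in expectation of life for one covariate pattern
#'
#' Computes, over a common horizon \eqn{\tau}:
#' \itemize{
#'   \item \eqn{E^*}: expected remaining life without cancer
#'     ([expected_life_remaining()], exact piecewise-exponential);
#'   \item \eqn{E_{obs}}: remaining life with cancer
#'     ([observed_life_expectancy()]);
#'   \item LEL \eqn{= E^* - E_{obs}} and PLL \eqn{= LEL / E^*}.
#' }
#' Using the same \eqn{\tau} for both integrals makes PLL a true fraction of
#' expected remaining life.
#'
#' @inheritParams observed_life_expectancy
#' @return an object of class `lel_result` with fields `profile`, `E_star`,
#'   `E_obs`, `LEL`, `PLL`, `tau`, `gl_order`, `tail_slope`.
#' @export
loss_in_expectation <- function(model, table, profile, tau = NULL,
                                gl_order = 15) {
  profile <- as_profile(profile)
  if (is.null(tau)) tau <- default_tau(table, profile)
  E_star <- expected_life_remaining(table, profile, tau)
  if (E_star <= 0) stop("degenerate profile: expected remaining life is 0")
  E_obs <- observed_life_expectancy(model, table, profile, tau, gl_order)
  structure(list(profile = profile, E_star = E_star, E_obs = E_obs,
                 LEL = E_star - E_obs, PLL = (E_star - E_obs) / E_star,
                 tau = tau, gl_order = gl_order,
                 tail_slope = tail_slope(model, profile)),
            class = "lel_result")
}

#' @export
print.lel_result <- function(x, ...) {
  p <- x$profile
  cat(sprintf("Profile: age %.1f, sex %s, deprivation %d, diagnosed %.1f\n",
              p$age, p$sex, p$dep, p$dx_year))
  cat(sprintf("  E* (no cancer)  %8.3f years\n", x$E_star))
  cat(sprintf("  E  (with cancer)%8.3f years\n", x$E_obs))
  cat(sprintf("  LEL             %8.3f years\n", x$LEL))
  cat(sprintf("  PLL             %8.1f %%\n", 100 * x$PLL))
  cat(sprintf("  (horizon %.1f y, GL order %d, tail slope %.3f)\n",
              x$tau, x$gl_order, x$tail_slope))
  invisible(x)
}

#' Loss in expectation of life across an age grid
#'
#' Vectorises [loss_in_expectation()] over ages at diagnosis for one sex,
#' deprivation quintile and diagnosis year; the `E_star` column is the
#' general-population life expectancy curve usually drawn alongside.
#'
#' @param model a fitted [relsurv_fpm()].
#' @param table a [life_table()].
#' @param ages numeric vector of ages at diagnosis.
#' @param sex "M" or "F".
#' @param dep deprivation quintile 1-5.
#' @param dx_year diagnosis year for predictions (decimal year).
#' @param tau,gl_order see [observed_life_expectancy()]; `tau = NULL` uses
#'   the per-age default horizon.
#' @return data frame with columns `age`, `E_star`, `E_obs`, `LEL`, `PLL`,
#'   `tail_slope`.
#' @export
age_profile <- function(model, table, ages, sex, dep, dx_year = 2013.0,
                        tau = NULL, gl_order = 15) {
  if (any(ages < 0) || any(ages >= table$age_cap + 1))
    stop("ages outside the life-table support [0, age_cap]")
  n_extrap <- 0L
  rows <- withCallingHandlers(
    lapply(ages, function(a) {
      r <- loss_in_expectation(model, table,
                               patient_profile(a, sex, dep, dx_year),
                               tau = tau, gl_order = gl_order)
      data.frame(age = a, E_star = r$E_star, E_obs = r$E_obs, LEL = r$LEL,
                 PLL = r$PLL, tail_slope = r$tail_slope)
    }),
    warning = function(w) {
      if (grepl("age-spline boundary", conditionMessage(w))) {
        n_extrap <<- n_extrap + 1L
        invokeRestart("muffleWarning")
      }
    })
  if (n_extrap > 0L)
    warning(n_extrap, " age(s) outside the age-spline boundary knots; ",
            "their predictions use the linear tail", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
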