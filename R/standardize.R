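#' Age-standardisation weight scheme
#'
#' Holds non-negative weights over age strata; weights are normalised to
#' sum to one.  Strata are either single years of age (column `age`) or
#' arbitrary bands (columns `age_lo`, `age_hi`, inclusive), e.g. the
#' International Cancer Survival Standard bands 15-44/45-54/55-64/65-74/75+
#' with user-supplied weight values.
#'
#' @param weights data frame with column `weight` plus either `age` or
#'   `age_lo`/`age_hi`.
#' @param kind one of `"internal"`, `"external_pooled"`,
#'   `"external_custom"`.
#' @param reference_year the cohort year the weights describe.
#' @return an object of class `weight_scheme`.
#' @export
weight_scheme <- function(weights, kind = "external_custom",
                          reference_year = 2013L) {
  kind <- match.arg(kind, c("internal", "external_pooled", "external_custom"))
  banded <- all(c("age_lo", "age_hi") %in% names(weights))
  if (!banded && !"age" %in% names(weights))
    stop("weights need an 'age' column or 'age_lo'/'age_hi' columns")
  if (!"weight" %in% names(weights)) stop("weights need a 'weight' column")
  if (any(weights$weight < 0)) stop("weights must be >= 0")
  s <- sum(weights$weight)
  if (s <= 0) stop("weights sum to 0")
  weights$weight <- weights$weight / s
  structure(list(weights = weights, kind = kind, banded = banded,
                 reference_year = reference_year),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("Age-standardisation weights (", x$kind, ", reference year ",
      x$reference_year, ")\n", sep = "")
  print(x$weights, row.names = FALSE)
  invisible(x)
}

#' Internal (or pooled) standardisation weights from a cohort
#'
#' Weights proportional to the number of diagnoses in `year` per single
#' year of age, within one deprivation quintile (`internal_weights`) or
#' pooled over all quintiles (`pooled_weights`).  Record order is
#' irrelevant.
#'
#' @param records registry data frame (see [read_registry()]).
#' @param dep deprivation quintile 1-5.
#' @param year diagnosis year defining the cohort (records with
#'   `floor(date_dx) == year`).
#' @return a [weight_scheme()].
#' @export
internal_weights <- function(records, dep, year = 2013L) {
  sub <- records[records$dep == dep & floor(records$date_dx) == year, ]
  if (nrow(sub) == 0L)
    stop("no diagnoses in ", year, " for deprivation quintile ", dep)
  tab <- table(floor(sub$age_dx))
  weight_scheme(data.frame(age = as.integer(names(tab)),
                           weight = as.numeric(tab)),
                kind = "internal", reference_year = year)
}

#' @rdname internal_weights
#' @export
pooled_weights <- function(records, year = 2013L) {
  sub <- records[floor(records$date_dx) == year, ]
  if (nrow(sub) == 0L) stop("no diagnoses in ", year)
  tab <- table(floor(sub$age_dx))
  ws <- weight_scheme(data.frame(age = as.integer(names(tab)),
                                 weight = as.numeric(tab)),
                      kind = "external_pooled", reference_year = year)
  ws
}

#' Weighted average of age-specific estimates
#'
#' `mean_LEL` is always the weighted mean of the age-specific losses.  For
#' the proportional measure two conventions exist and both are available:
#' the weighted mean of the age-specific ratios (`"mean_of_ratios"`, the
#' default) or the ratio of weighted means
#' \eqn{\sum w\,LEL / \sum w\,E^*} (`"ratio_of_means"`, needs an `E_star`
#' column).
#'
#' @param results data frame with columns `age`, `LEL`, `PLL` (and `E_star`
#'   for `"ratio_of_means"`), e.g. from [age_profile()].
#' @param scheme a [weight_scheme()]; single-year strata must match the
#'   result ages exactly (a mismatch error lists the symmetric difference),
#'   banded strata average the result ages falling inside each band.
#' @param pll one of `"mean_of_ratios"`, `"ratio_of_means"`.
#' @return list with `mean_LEL` and `mean_PLL`.
#' @export
standardized_average <- function(results, scheme,
                                 pll = c("mean_of_ratios", "ratio_of_means")) {
  stopifnot(inherits(scheme, "weight_scheme"))
  pll <- match.arg(pll)
  w <- scheme$weights
  if (!scheme$banded) {
    extra <- setdiff(results$age, w$age)
    miss <- setdiff(w$age, results$age)
    if (length(miss) > 0 || length(extra) > 0)
      stop("age strata mismatch; in scheme but not results: ",
           paste(miss, collapse = ", "), "; in results but not scheme: ",
           paste(extra, collapse = ", "))
    m <- merge(w, results, by = "age")
    lel <- m$LEL; pllv <- m$PLL; es <- m$E_star; ww <- m$weight
  } else {
    band <- function(col) vapply(seq_len(nrow(w)), function(i) {
      inb <- results$age >= w$age_lo[i] & results$age <= w$age_hi[i]
      if (!any(inb)) stop("no result ages inside band [", w$age_lo[i], ", ",
                          w$age_hi[i], "]")
      mean(results[[col]][inb])
    }, numeric(1))
    lel <- band("LEL"); pllv <- band("PLL")
    es <- if ("E_star" %in% names(results)) band("E_star") else NULL
    ww <- w$weight
  }
  mean_LEL <- sum(ww * lel)
  mean_PLL <- if (pll == "mean_of_ratios") sum(ww * pllv) else {
    if (is.null(es)) stop("ratio_of_means needs an E_star column")
    sum(ww * lel) / sum(ww * es)
  }
  list(mean_LEL = mean_LEL, mean_PLL = mean_PLL)
}

#' Total life-years lost for an annual cohort
#'
#' The population burden: number of patients diagnosed in the reference
#' year times the average loss in expectation of life.
#'
#' @param n_2013 patient count (>= 0).
#' @param mean_lel average loss in expectation of life (years).
#' @return total years lost.
#' @export
total_years_lost <- function(n_2013, mean_lel) {
  if (any(n_2013 < 0)) stop("patient count must be >= 0")
  n_2013 * mean_lel
}

#' Standardised summary per cancer, sex and deprivation quintile
#'
#' For every cancer type and sex in the cohort and every deprivation
#' quintile: builds the standardisation weights from the reference-year
#' diagnoses, computes age-specific loss in expectation of life from the
#' fitted model, averages, and multiplies by the reference-year count to
#' get total life-years lost.
#'
#' @param models nested named list `models[[cancer]][[sex]]` of fitted
#'   [relsurv_fpm()] objects.
#' @param table a [life_table()].
#' @param cohort registry data frame (post [first_tumour_filter()]).
#' @param weights `"internal"` (per-quintile 2013 age distribution),
#'   `"pooled"` (all quintiles pooled), or a [weight_scheme()] applied to
#'   every stratum.
#' @param year reference diagnosis year.
#' @param average `"by-age"` (age-specific estimates at single years of
#'   age, then weighted) or `"per-patient"` (mean over every reference-year
#'   patient's exact profile; equivalent to internal weighting at full age
#'   resolution).
#' @param dx_year diagnosis date used for model predictions.
#' @param pll see [standardized_average()].
#' @param tau,gl_order see [observed_life_expectancy()].
#' @return data frame of class `standardized_summary` with columns
#'   `cancer`, `sex`, `dep`, `N_2013`, `mean_LEL`, `mean_PLL`,
#'   `total_years_lost`, ordered by cancer, sex, quintile.
#' @export
summary_table <- function(models, table, cohort, weights = "internal",
                          year = 2013L, average = c("by-age", "per-patient"),
                          dx_year = 2013.0,
                          pll = c("mean_of_ratios", "ratio_of_means"),
                          tau = NULL, gl_order = 15) {
  average <- match.arg(average)
  pll <- match.arg(pll)
  cancers <- sort(unique(cohort$cancer))
  rows <- list()
  for (cz in cancers) {
    sub_c <- cohort[cohort$cancer == cz, ]
    for (sx in sort(unique(sub_c$sex))) {
      if (is.null(models[[cz]]) || is.null(models[[cz]][[sx]]))
        stop("no model supplied for cancer '", cz, "', sex '", sx, "'")
      fit <- models[[cz]][[sx]]
      sub_s <- sub_c[sub_c$sex == sx, ]
      for (dep in 1:5) {
        sub <- sub_s[sub_s$dep == dep & floor(sub_s$date_dx) == year, ]
        N <- nrow(sub)
        if (average == "per-patient") {
          if (N == 0L)
            stop("no diagnoses in ", year, " for quintile ", dep)
          res <- vapply(seq_len(N), function(i) {
            r <- loss_in_expectation(
              fit, table,
              patient_profile(sub$age_dx[i], sx, dep, dx_year),
              tau = tau, gl_order = gl_order)
            c(r$LEL, r$PLL)
          }, numeric(2))
          mean_LEL <- mean(res[1, ]); mean_PLL <- mean(res[2, ])
        } else {
          ws <- if (inherits(weights, "weight_scheme")) weights
                else if (weights == "internal") internal_weights(sub_s, dep, year)
                else if (weights == "pooled") pooled_weights(sub_s, year)
                else stop("unknown weights: ", weights)
          ages <- if (ws$banded)
            sort(unique(floor(sub_s$age_dx[floor(sub_s$date_dx) == year])))
          else ws$weights$age
          prof <- age_profile(fit, table, ages, sx, dep, dx_year,
                              tau = tau, gl_order = gl_order)
          avg <- standardized_average(prof, ws, pll = pll)
          mean_LEL <- avg$mean_LEL; mean_PLL <- avg$mean_PLL
        }
        rows[[length(rows) + 1L]] <- data.frame(
          cancer = cz, sex = sx, dep = dep, N_2013 = N,
          mean_LEL = mean_LEL, mean_PLL = mean_PLL,
          total_years_lost = total_years_lost(N, mean_LEL))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("standardized_summary", "data.frame")
  out
}
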