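#' Population life table of annual mortality rates
#'
#' Validates and indexes a table of expected (background) mortality rates
#' stratified by sex, deprivation quintile, single year of age and calendar
#' year.  Rates are hazards (events per person-year), not probabilities.
#'
#' The table must be rectangular: every combination of the sexes present,
#' deprivation quintiles 1-5, ages `0:age_cap` and calendar years
#' `min_year:max_year` must appear exactly once.  Attained ages beyond
#' `age_cap` reuse the `age_cap` row; attained years outside the tabulated
#' range are clamped to the nearest tabulated year (in particular, beyond
#' the last year the last year's rates are carried forward — a
#' constant-future assumption appropriate when extrapolating decades ahead).
#'
#' @param x data frame with columns `sex` ("M"/"F"), `dep` (1-5), `age`
#'   (integer, from 0), `year` (integer calendar year), `rate` (>= 0).
#' @return an object of class `life_table`.
#' @seealso [read_life_table()], [expected_hazard()], [expected_survival()],
#'   [expected_life_remaining()]
#' @export
life_table <- function(x) {
  need <- c("sex", "dep", "age", "year", "rate")
  if (!all(need %in% names(x)))
    stop("life table needs columns: ", paste(need, collapse = ", "))
  x$sex <- as.character(x$sex)
  sexes <- sort(unique(x$sex))
  if (!all(sexes %in% c("F", "M"))) stop("sex must be coded 'M' or 'F'")
  deps <- sort(unique(x$dep))
  if (!all(deps %in% 1:5)) stop("dep must be a quintile in 1..5")
  if (!identical(as.integer(deps), 1:5))
    stop("life table must cover all deprivation quintiles 1..5")
  ages <- sort(unique(x$age))
  age_cap <- max(ages)
  if (!identical(as.integer(ages), 0:age_cap))
    stop("ages must be contiguous integers starting at 0")
  if (age_cap < 99) stop("life table must tabulate ages to at least 99")
  years <- sort(unique(x$year))
  if (!identical(as.integer(years), as.integer(years[1]:years[length(years)])))
    stop("calendar years must be contiguous")
  if (any(!is.finite(x$rate))) stop("non-finite rate in life table")
  if (any(x$rate < 0)) {
    bad <- x[x$rate < 0, ][1, ]
    stop(sprintf("negative rate at (sex=%s, dep=%d, age=%d, year=%d)",
                 bad$sex, bad$dep, bad$age, bad$year))
  }

  n_expect <- length(sexes) * 5L * (age_cap + 1L) * length(years)
  if (nrow(x) > n_expect) {
    key <- paste(x$sex, x$dep, x$age, x$year)
    dup <- key[duplicated(key)][1]
    stop("duplicate life-table key: (sex dep age year) = ", dup)
  }
  arr <- array(NA_real_,
               dim = c(length(sexes), 5L, age_cap + 1L, length(years)),
               dimnames = list(sexes, 1:5, 0:age_cap, years))
  idx <- cbind(match(x$sex, sexes), x$dep, x$age + 1L, x$year - years[1] + 1L)
  arr[idx] <- x$rate
  if (anyNA(arr)) {
    miss <- which(is.na(arr), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "ragged life table: missing (sex=%s, dep=%s, age=%s, year=%s)",
      sexes[miss[1]], miss[2], miss[3] - 1L, years[miss[4]]))
  }
  structure(list(rates = arr, sexes = sexes, age_cap = age_cap,
                 year_range = c(years[1], years[length(years)])),
            class = "life_table")
}

#' Read a population life table from a delimited file
#'
#' Expects a header row and columns `sex,dep,age,year,rate`; see
#' [life_table()] for the validation rules.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return a validated `life_table`.
#' @export
read_life_table <- function(path, sep = ",") {
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  life_table(x)
}

#' @export
print.life_table <- function(x, ...) {
  cat("Population life table\n")
  cat("  sexes:", paste(x$sexes, collapse = ", "),
      " deprivation quintiles: 1-5\n")
  cat("  ages: 0-", x$age_cap, "  years: ", x$year_range[1], "-",
      x$year_range[2], "\n", sep = "")
  cat("  rate range:", format(range(x$rates), digits = 4), "\n")
  invisible(x)
}

#' Covariate profile for life-table and model predictions
#'
#' @param age age at diagnosis in years (continuous, >= 0, below the life
#'   table's age cap).
#' @param sex "M" or "F".
#' @param dep deprivation quintile, 1 (least deprived) to 5 (most deprived).
#' @param dx_year diagnosis date as a decimal calendar year
#'   (2007.0 = 1 January 2007).
#' @return an object of class `patient_profile`.
#' @export
patient_profile <- function(age, sex, dep, dx_year) {
  stopifnot(length(age) == 1L, length(sex) == 1L, length(dep) == 1L,
            length(dx_year) == 1L)
  if (!is.finite(age) || age < 0) stop("age must be >= 0")
  if (!sex %in% c("M", "F")) stop("sex must be 'M' or 'F'")
  if (!dep %in% 1:5) stop("dep must be in 1..5")
  structure(list(age = as.numeric(age), sex = sex, dep = as.integer(dep),
                 dx_year = as.numeric(dx_year)),
            class = "patient_profile")
}

as_profile <- function(p) {
  if (inherits(p, "patient_profile")) return(p)
  patient_profile(p$age, p$sex, p$dep, p$dx_year)
}

# Raw rate lookup for attained-age / attained-year vectors (already floored).
lt_rate <- function(table, sex, dep, age, year) {
  age <- pmin(age, table$age_cap)
  year <- pmin(pmax(year, table$year_range[1]), table$year_range[2])
  si <- match(sex, table$sexes)
  if (anyNA(si)) stop("sex not present in life table")
  n <- max(length(age), length(year), length(si), length(dep))
  idx <- cbind(rep_len(si, n), rep_len(dep, n), rep_len(age, n) + 1L,
               rep_len(year, n) - table$year_range[1] + 1L)
  table$rates[idx]
}

#' Expected (background) mortality rate for a profile
#'
#' Returns the life-table hazard at attained age `floor(age + t)` (capped at
#' the table's oldest age) and attained calendar year `floor(dx_year + t)`
#' (clamped to the tabulated range; beyond the last year the last year's
#' rates are reused).
#'
#' @param table a [life_table()].
#' @param profile a [patient_profile()] (or list with the same fields).
#' @param t time since diagnosis in years (vectorised, >= 0).
#' @return numeric vector of annual rates.
#' @export
expected_hazard <- function(table, profile, t) {
  profile <- as_profile(profile)
  if (any(t < 0)) stop("t must be >= 0")
  if (profile$age >= table$age_cap + 1)
    stop("age at diagnosis is beyond the life-table age cap")
  lt_rate(table, profile$sex, profile$dep,
          floor(profile$age + t), floor(profile$dx_year + t))
}

# Piecewise-constant hazard path for a profile out to tau.  Segment
# boundaries fall at every integer attained age and every 1 January.
# Returns start, end, rate, plus the cumulative hazard and survival at each
# segment start, so downstream integrals are exact within segments.
lt_path <- function(table, profile, tau) {
  profile <- as_profile(profile)
  if (tau <= 0) stop("tau must be > 0")
  age_b <- seq(floor(profile$age) + 1, by = 1,
               length.out = max(0, ceiling(tau + profile$age - floor(profile$age)))) - profile$age
  yr_b <- seq(floor(profile$dx_year) + 1, by = 1,
              length.out = max(0, ceiling(tau + profile$dx_year - floor(profile$dx_year)))) - profile$dx_year
  inner <- c(age_b, yr_b)
  inner <- sort(unique(round(inner[inner > 1e-9 & inner < tau - 1e-9], 9)))
  b <- c(0, inner, tau)
  start <- b[-length(b)]
  end <- b[-1]
  mid <- (start + end) / 2
  rate <- lt_rate(table, profile$sex, profile$dep,
                  floor(profile$age + mid), floor(profile$dx_year + mid))
  H_start <- c(0, cumsum(rate * (end - start)))[seq_along(start)]
  list(start = start, end = end, rate = rate,
       H_start = H_start, S_start = exp(-H_start))
}

#' Expected survival from population rates
#'
#' \eqn{S^*(t) = \exp(-\int_0^t h^*(u)\,du)} computed exactly as a
#' piecewise-exponential product over the segments on which attained age and
#' attained calendar year are both constant.
#'
#' @inheritParams expected_hazard
#' @return numeric vector of survival probabilities, `S*(0) = 1`.
#' @export
expected_survival <- function(table, profile, t) {
  if (any(t < 0)) stop("t must be >= 0")
  if (length(t) == 0L) return(numeric(0))
  tmax <- max(t)
  if (tmax == 0) return(rep(1, length(t)))
  path <- lt_path(table, profile, tmax)
  i <- findInterval(t, path$start, rightmost.closed = FALSE)
  i[i < 1L] <- 1L
  path$S_start[i] * exp(-path$rate[i] * (t - path$start[i]))
}

#' Expected remaining life years (no cancer)
#'
#' \eqn{E^* = \int_0^\tau S^*(t)\,dt} by the exact piecewise-exponential
#' closed form: a segment of length \eqn{\Delta} with rate \eqn{r} entered
#' with survival \eqn{S_0} contributes \eqn{S_0 (1 - e^{-r\Delta})/r}
#' (limit \eqn{S_0 \Delta} as \eqn{r \to 0}).
#'
#' @inheritParams expected_hazard
#' @param tau integration horizon in years; defaults to
#'   `age_cap + 1 - age + 20` so the expected survival has decayed to
#'   essentially zero for realistic rates.
#' @return expected remaining life in years.
#' @export
expected_life_remaining <- function(table, profile, tau = NULL) {
  profile <- as_profile(profile)
  if (is.null(tau)) tau <- default_tau(table, profile)
  if (tau <= 0) stop("tau must be > 0")
  path <- lt_path(table, profile, tau)
  dl <- path$end - path$start
  r <- path$rate
  seg <- ifelse(r > 0, path$S_start * (1 - exp(-r * dl)) / ifelse(r > 0, r, 1),
                path$S_start * dl)
  sum(seg)
}

default_tau <- function(table, profile) {
  table$age_cap + 1 - profile$age + 20
}
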