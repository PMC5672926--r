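#' Read a person-level registry file
#'
#' Delimited text with header `id,cancer,sex,dep,age_dx,date_dx,date_exit,event`.
#' Dates are decimal calendar years (2007.5 = mid-2007); `event` is 1 for
#' death from any cause, 0 for censoring.
#'
#' @param path file path.
#' @param sep field separator.
#' @return data frame of person records.
#' @export
read_registry <- function(path, sep = ",") {
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  validate_records(x)
}

validate_records <- function(x) {
  need <- c("id", "cancer", "sex", "dep", "age_dx", "date_dx", "date_exit",
            "event")
  if (!all(need %in% names(x)))
    stop("registry needs columns: ", paste(need, collapse = ", "))
  if (any(!x$dep %in% 1:5)) stop("dep must be in 1..5")
  if (any(x$age_dx < 0)) stop("age_dx must be >= 0")
  if (any(x$date_exit < x$date_dx)) stop("date_exit before date_dx")
  if (any(!x$event %in% 0:1)) stop("event must be 0 or 1")
  x
}

#' Keep only the first tumour per person and cancer type
#'
#' For each `(id, cancer)` pair the record with the earliest diagnosis date
#' is retained; ties are broken deterministically by input order.
#'
#' @param records registry data frame (see [read_registry()]).
#' @return filtered data frame, original row order preserved.
#' @export
first_tumour_filter <- function(records) {
  if (nrow(records) == 0L) return(records)
  key <- paste(records$id, records$cancer, sep = "\r")
  ord <- order(key, records$date_dx, seq_len(nrow(records)))
  keep_sorted <- !duplicated(key[ord])
  keep <- logical(nrow(records))
  keep[ord] <- keep_sorted
  records[keep, , drop = FALSE]
}

#' Build the period-analysis dataset with delayed entry
#'
#' Restricts to person-time falling inside the calendar window
#' `[w_start, w_end)` (the default, 2007.0 to 2014.0, means "under follow-up
#' at any point from 1 January 2007 through 31 December 2013").  Records
#' that exited on or before `w_start` or were diagnosed at/after `w_end`
#' are dropped; follow-up is censored at `w_end`; entry time is
#' `max(0, w_start - date_dx)` on the time-since-diagnosis scale.
#' Zero-length follow-up (same-day death) is extended by one day
#' (1/365.25 y) before clipping so the likelihood sees a positive interval.
#'
#' @param records registry data frame.
#' @param w_start,w_end window bounds as decimal years; `w_end` is exclusive.
#' @param verbose if `TRUE`, message the number of rows dropped because
#'   clipping left them with no person-time in the window.
#' @return an object of class `period_dataset`: the retained records plus
#'   columns `t0` (entry), `t` (exit) and `d` (event in window), and a
#'   `window` attribute.
#' @export
make_period_dataset <- function(records, w_start = 2007.0, w_end = 2014.0,
                                verbose = FALSE) {
  if (w_end <= w_start) stop("w_end must be > w_start")
  records <- validate_records(records)
  exit <- records$date_exit
  same_day <- exit == records$date_dx
  exit[same_day] <- exit[same_day] + 1 / 365.25

  keep <- exit > w_start & records$date_dx < w_end
  x <- records[keep, , drop = FALSE]
  exit <- exit[keep]

  d <- x$event
  d[exit > w_end] <- 0L
  t1 <- pmin(exit, w_end) - x$date_dx
  t0 <- pmax(0, w_start - x$date_dx)

  pos <- t1 > t0
  n_zero <- sum(!pos)
  if (n_zero > 0L && verbose)
    message(n_zero, " record(s) dropped: no person-time inside the window")
  x <- x[pos, , drop = FALSE]
  x$t0 <- t0[pos]
  x$t <- t1[pos]
  x$d <- as.integer(d[pos])
  rownames(x) <- NULL
  structure(x, window = c(w_start, w_end), n_dropped_zero = n_zero,
            class = c("period_dataset", "data.frame"))
}

#' @export
print.period_dataset <- function(x, ...) {
  w <- attr(x, "window")
  cat("Period-analysis dataset: ", nrow(x), " subjects, window [",
      w[1], ", ", w[2], ")\n", sep = "")
  cat("  events:", sum(x$d), " delayed entry:", sum(x$t0 > 0), "\n")
  invisible(as.data.frame(x))
}
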