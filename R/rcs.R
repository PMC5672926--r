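#' Restricted cubic spline specification
#'
#' Defines a restricted cubic spline by its knot vector on the working scale
#' (log time since diagnosis for baseline and time-dependent effects, years of
#' age for the age effect).  With \eqn{K} knots the basis has \eqn{K - 1}
#' columns; the spline is constrained to be linear beyond the boundary knots,
#' which is what makes extrapolation on the transformed scale well behaved.
#' \eqn{K = 2} degenerates to a single linear column.
#'
#' @param knots numeric vector of at least two strictly increasing knots.
#' @return an object of class `rcs_spec`.
#' @export
rcs_spec <- function(knots) {
  knots <- as.numeric(knots)
  if (length(knots) < 2L) stop("an rcs_spec needs at least 2 knots")
  if (any(!is.finite(knots))) stop("knots must be finite")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  structure(list(knots = knots), class = "rcs_spec")
}

#' @export
print.rcs_spec <- function(x, ...) {
  cat("Restricted cubic spline:", length(x$knots), "knots at",
      paste(signif(x$knots, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Restricted cubic spline basis
#'
#' Evaluates the truncated-power restricted cubic spline basis
#' \deqn{[x,\; v_2(x),\; \dots,\; v_{K-1}(x)]}
#' with
#' \deqn{v_j(x) = (x-k_j)_+^3 - \lambda_j (x-k_1)_+^3 - (1-\lambda_j)(x-k_K)_+^3,
#'   \quad \lambda_j = \frac{k_K - k_j}{k_K - k_1}.}
#' The restriction makes the curve linear for \eqn{x < k_1} and \eqn{x > k_K}.
#'
#' @param x numeric vector of evaluation points.
#' @param spec an [rcs_spec()].
#' @return numeric matrix, `length(x)` rows by `K - 1` columns.
#' @export
rcs_basis <- function(x, spec) {
  stopifnot(inherits(spec, "rcs_spec"))
  k <- spec$knots
  K <- length(k)
  out <- matrix(0, length(x), K - 1L)
  out[, 1L] <- x
  if (K > 2L) {
    kmin <- k[1L]; kmax <- k[K]
    p1 <- pmax(x - kmin, 0)^3
    pK <- pmax(x - kmax, 0)^3
    for (j in 2L:(K - 1L)) {
      lam <- (kmax - k[j]) / (kmax - kmin)
      out[, j] <- pmax(x - k[j], 0)^3 - lam * p1 - (1 - lam) * pK
    }
  }
  out
}

#' Derivative of the restricted cubic spline basis
#'
#' Elementwise derivative of [rcs_basis()] with respect to `x`.  Outside the
#' boundary knots each column's derivative is constant (the linear tails),
#' and the first column's derivative is identically 1.
#'
#' @inheritParams rcs_basis
#' @return numeric matrix matching the shape of [rcs_basis()].
#' @export
rcs_deriv <- function(x, spec) {
  stopifnot(inherits(spec, "rcs_spec"))
  k <- spec$knots
  K <- length(k)
  out <- matrix(0, length(x), K - 1L)
  out[, 1L] <- 1
  if (K > 2L) {
    kmin <- k[1L]; kmax <- k[K]
    d1 <- 3 * pmax(x - kmin, 0)^2
    dK <- 3 * pmax(x - kmax, 0)^2
    for (j in 2L:(K - 1L)) {
      lam <- (kmax - k[j]) / (kmax - kmin)
      out[, j] <- 3 * pmax(x - k[j], 0)^2 - lam * d1 - (1 - lam) * dK
    }
  }
  out
}

# Knot vector from data quantiles.  df = number of basis columns = K - 1.
# boundary_probs places the outer knots; interior knots sit at equally
# spaced quantiles in between.
knots_from_data <- function(x, df, boundary_probs = c(0, 1)) {
  if (df < 1L) stop("df must be >= 1")
  probs <- seq(boundary_probs[1L], boundary_probs[2L], length.out = df + 1L)
  k <- unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))
  k <- unique(k)
  if (length(k) < 2L) stop("degenerate data: cannot place at least 2 distinct knots")
  k
}
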