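#' Percentile knots for a restricted quadratic spline
#'
#' Computes knot locations as sample percentiles (linear interpolation between
#' order statistics, the \code{stats::quantile} type-7 default), the
#' convention used for the 4-knot age spline at the 20th, 40th, 60th and 80th
#' percentiles.
#'
#' @param values Numeric vector (missing values dropped); at least 20
#'   non-missing values are required for stable percentile knots.
#' @param probs Percentile targets in (0, 1); default
#'   \code{c(.2, .4, .6, .8)}.
#' @return Object of class \code{"rq_spline"}: list with \code{knots} and
#'   \code{probs}.
#' @export
rq_spline_knots <- function(values, probs = c(0.2, 0.4, 0.6, 0.8)) {
  values <- values[!is.na(values)]
  if (length(values) < 20) {
    stop("need at least 20 non-missing values to place percentile knots",
         call. = FALSE)
  }
  if (any(diff(probs) <= 0)) stop("probs must be strictly increasing",
                                  call. = FALSE)
  knots <- unname(stats::quantile(values, probs = probs, type = 7))
  if (any(diff(knots) <= 0)) {
    stop("tied percentile values produce non-distinct knots: ",
         paste(signif(knots, 6), collapse = ", "), call. = FALSE)
  }
  structure(list(knots = knots, probs = probs), class = "rq_spline")
}

#' Restricted quadratic spline basis
#'
#' Basis for a quadratic spline that is linear below the first knot and
#' linear above the last knot, with continuous first derivative everywhere.
#' With knots \eqn{k_1 < k_2 < k_3 < k_4} the basis columns are \eqn{x} and
#' \deqn{s_j(x) = \frac{(x-k_j)_+^2 - (x-k_4)_+^2}{k_4 - k_1}, \quad j = 1, 2,}
#' the third truncated term being omitted to impose linearity in the upper
#' tail. Each \eqn{s_j} is zero below \eqn{k_1}, quadratic between \eqn{k_j}
#' and \eqn{k_4}, and exactly linear beyond \eqn{k_4} (the two squares cancel
#' to a linear function), so the whole spline has zero curvature outside
#' \eqn{[k_1, k_4]}.
#'
#' @param x Numeric vector.
#' @param spec An \code{"rq_spline"} object from [rq_spline_knots()], or a
#'   numeric vector of 4 strictly increasing knots.
#' @return Numeric matrix with \code{length(x)} rows and 3 columns
#'   (\code{x}, \code{s1}, \code{s2}). Extrapolation is allowed and stays
#'   linear.
#' @export
rq_spline_basis <- function(x, spec) {
  knots <- if (inherits(spec, "rq_spline")) spec$knots else as.numeric(spec)
  if (length(knots) != 4 || any(diff(knots) <= 0)) {
    stop("spec must supply 4 strictly increasing knots", call. = FALSE)
  }
  k4 <- knots[4]
  scale <- k4 - knots[1]
  pp <- function(v) pmax(v, 0)^2
  tail4 <- pp(x - k4)
  out <- cbind(
    x = x,
    s1 = (pp(x - knots[1]) - tail4) / scale,
    s2 = (pp(x - knots[2]) - tail4) / scale
  )
  out
}
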