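#' Viability-fecundity trade-off curve of a single cell
#'
#' A trade-off curve `phi` gives the maximal viability a cell can attain at a
#' given fecundity investment `b`. It is continuous on `[0, b_max]`, strictly
#' decreasing on `(0, b_max)`, with `phi(0) = v_max > 0` and `phi(b_max) = 0`.
#' Its curvature is the key life-history parameter: concave curves describe
#' small colonies with low initial reproduction costs, convex curves describe
#' large colonies with high initial costs, linear curves sit in between.
#'
#' The three parametric families are fully determined by `(v_max, b_max)`:
#' \describe{
#'   \item{`quadratic_concave`}{`phi(b) = v_max * (1 - (b/b_max)^2)`}
#'   \item{`linear`}{`phi(b) = v_max * (1 - b/b_max)`, i.e. slope
#'     `gamma = v_max / b_max`}
#'   \item{`quadratic_convex`}{`phi(b) = v_max * (1 - b/b_max)^2`}
#' }
#' A `custom` form takes `phi` (and optionally `dphi`) as functions; the curve
#' is validated by sampling (monotone decreasing, correct endpoints) and its
#' derivative, when not supplied, is approximated by central finite differences
#' with step `1e-6 * b_max`.
#'
#' @param form curvature family.
#' @param v_max maximal viability, `phi(0)`; must be positive and finite.
#' @param b_max maximal fecundity; must be positive and finite.
#' @param phi,dphi for `form = "custom"`, the curve and (optionally) its
#'   derivative, as functions of `b`.
#' @return an object of class `"tradeoff"`.
#' @examples
#' tr <- tradeoff("quadratic_concave", v_max = 6, b_max = sqrt(2)) # 6 - 3 b^2
#' phi_at(tr, c(0, 1, sqrt(2)))
#' @export
tradeoff <- function(form = c("quadratic_concave", "linear", "quadratic_convex",
                              "custom"),
                     v_max, b_max, phi = NULL, dphi = NULL) {
  form <- match.arg(form)
  if (!is.numeric(v_max) || length(v_max) != 1L || !is.finite(v_max) || v_max <= 0)
    stop("'v_max' must be a single finite positive number")
  if (!is.numeric(b_max) || length(b_max) != 1L || !is.finite(b_max) || b_max <= 0)
    stop("'b_max' must be a single finite positive number")
  if (form == "custom") {
    if (!is.function(phi)) stop("custom trade-off requires a 'phi' function")
    tol <- 1e-6 * max(1, v_max)
    if (abs(phi(0) - v_max) > tol)
      stop("custom trade-off: phi(0) must equal v_max")
    if (abs(phi(b_max)) > tol)
      stop("custom trade-off: phi(b_max) must equal 0")
    bs <- seq(0, b_max, length.out = 101L)
    vals <- vapply(bs, phi, numeric(1))
    if (any(diff(vals) > tol))
      stop("custom trade-off: phi must be strictly decreasing on (0, b_max)")
  } else {
    phi <- NULL
    dphi <- NULL
  }
  structure(list(form = form, v_max = v_max, b_max = b_max,
                 phi = phi, dphi = dphi),
            class = "tradeoff")
}

#' Evaluate a trade-off curve
#'
#' @param tr a [tradeoff()] object.
#' @param b fecundity value(s) in `[0, b_max]`.
#' @return viability value(s) `phi(b)`.
#' @export
phi_at <- function(tr, b) {
  stopifnot(inherits(tr, "tradeoff"))
  x <- b / tr$b_max
  switch(tr$form,
         quadratic_concave = tr$v_max * (1 - x^2),
         linear            = tr$v_max * (1 - x),
         quadratic_convex  = tr$v_max * (1 - x)^2,
         custom            = vapply(b, tr$phi, numeric(1)))
}

#' Slope of a trade-off curve
#'
#' Analytic for the parametric families; for custom curves uses the supplied
#' `dphi` or central finite differences with step `1e-6 * b_max`.
#'
#' @inheritParams phi_at
#' @return derivative value(s) `dphi/db` (negative on the open domain).
#' @export
dphi_at <- function(tr, b) {
  stopifnot(inherits(tr, "tradeoff"))
  switch(tr$form,
         quadratic_concave = -2 * tr$v_max * b / tr$b_max^2,
         linear            = rep(-tr$v_max / tr$b_max, length(b)),
         quadratic_convex  = -2 * tr$v_max / tr$b_max * (1 - b / tr$b_max),
         custom = {
           if (is.function(tr$dphi)) vapply(b, tr$dphi, numeric(1))
           else {
             h <- 1e-6 * tr$b_max
             lo <- pmax(b - h, 0); hi <- pmin(b + h, tr$b_max)
             (phi_at(tr, hi) - phi_at(tr, lo)) / (hi - lo)
           }
         })
}

## curvature class used for algorithm dispatch; custom curves are probed
## numerically at the domain midpoints
tradeoff_curvature <- function(tr) {
  switch(tr$form,
         quadratic_concave = "concave",
         linear = "linear",
         quadratic_convex = "convex",
         custom = {
           bs <- seq(0, tr$b_max, length.out = 41L)
           v <- phi_at(tr, bs)
           d2 <- diff(v, differences = 2L)
           tol <- 1e-9 * max(1, tr$v_max)
           if (all(d2 <= tol) && any(d2 < -tol)) "concave"
           else if (all(d2 >= -tol) && any(d2 > tol)) "convex"
           else if (all(abs(d2) <= tol)) "linear"
           else "mixed"
         })
}

## slope of a linear trade-off
tradeoff_gamma <- function(tr) tr$v_max / tr$b_max

#' @export
print.tradeoff <- function(x, ...) {
  cat(sprintf("trade-off curve [%s]: v_max = %.6g, b_max = %.6g\n",
              x$form, x$v_max, x$b_max))
  invisible(x)
}

## inverse of dphi on [0, b_max]: smallest b with dphi(b) = slope, clipped.
## Used by marginal-equalization (water-filling) routines. For concave curves
## dphi is decreasing in b; for convex curves it is increasing.
invert_dphi <- function(tr, slope) {
  L <- tr$b_max; v <- tr$v_max
  switch(tr$form,
         quadratic_concave = min(max(-slope * L^2 / (2 * v), 0), L),
         quadratic_convex  = min(max(L * (1 + slope * L / (2 * v)), 0), L),
         linear            = stop("linear trade-off has constant slope"),
         custom = {
           d0 <- dphi_at(tr, 0); dL <- dphi_at(tr, L)
           f <- function(b) dphi_at(tr, b) - slope
           if (f(0) * f(L) > 0) {
             ## slope outside attainable range: clip to the nearer endpoint
             if (abs(d0 - slope) < abs(dL - slope)) 0 else L
           } else stats::uniroot(f, c(0, L), tol = 1e-12 * L)$root
         })
}
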