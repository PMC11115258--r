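#' Natural cubic spline basis for the exposure term
#'
#' Thin wrapper around [splines::ns()].  With `df = 2` the basis has
#' boundary knots at the minimum and maximum of the fitting values and one
#' interior knot at their median; the natural constraint makes the fitted
#' curve linear beyond the boundary knots, and the span of
#' `{1, basis columns}` contains every linear function of the covariate.
#'
#' @param values Covariate values used for fitting (>= 3 distinct).
#' @param df Degrees of freedom (number of basis columns), default 2.
#' @return An `ns_basis` object (the evaluated basis matrix with knot
#'   attributes; evaluate at new points with [eval_basis()]).
#' @export
ns_basis <- function(values, df = 2) {
  if (length(unique(values)) < 3) {
    stop("need at least 3 distinct covariate values for a spline basis",
         call. = FALSE)
  }
  b <- splines::ns(values, df = df)
  class(b) <- c("ns_basis", class(b))
  b
}

#' Evaluate a spline basis at new covariate values
#'
#' @param basis An [ns_basis()].
#' @param newx Values inside the boundary-knot range (no extrapolation).
#' @return Basis matrix with one row per element of `newx`.
#' @export
eval_basis <- function(basis, newx) {
  bk <- attr(basis, "Boundary.knots")
  if (any(newx < bk[1] - 1e-9) || any(newx > bk[2] + 1e-9)) {
    stop(sprintf("values outside the basis domain [%g, %g]", bk[1], bk[2]),
         call. = FALSE)
  }
  cls <- class(basis)
  class(basis) <- setdiff(cls, "ns_basis")
  m <- stats::predict(basis, newx)
  unname(m)
}
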