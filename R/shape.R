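#' Supralinearity assessments
#'
#' Two operational tests of concentration-response shape:
#'
#' * **Slope-ratio test** — the fitted log hazard-ratio curve is evaluated
#'   at the lowest covariate value, the boundary between the lower and
#'   upper halves of the covariate values (their median), and the highest
#'   value.  Slope A is the average slope over the lower half, Slope B over
#'   the upper half.  Ratio A/B > 1.2 is classified supralinear, < 0.8
#'   sublinear, otherwise linear.
#' * **AIC-difference test** — linearity is rejected when the linear Cox
#'   model's AIC exceeds the spline Cox model's AIC by more than 2.
#'
#' For the measurement-error experiments the slope ratio is compared
#' against the same cohort's no-error fit ([relative_slope_change()]),
#' because sampling noise alone leaves the no-error curve imperfectly
#' linear.
#'
#' @name shape_tests
NULL

#' Slope-ratio test for supralinearity
#'
#' @param fit A `cox_grouped` fit (typically the spline fit), or a plain
#'   function mapping covariate values to log hazard ratios (useful for
#'   assessing noiseless model curves).
#' @param values Covariate values defining the halves (default the fit's
#'   own covariate values).
#' @param split `"median"`: boundary at the median of `values` (equal
#'   halves of the values); `"range_midpoint"`: boundary at the middle of
#'   the covariate range.
#' @param scale `"log_hr"` (default) computes slopes of the log
#'   hazard-ratio curve; `"hr"` of the hazard-ratio curve itself.
#' @param thresholds Length-2 vector `c(sublinear, supralinear)` of ratio
#'   cutoffs, default `c(0.8, 1.2)`; the closed interval between them is
#'   classified linear.
#' @param degeneracy_floor If `|slope_b|` falls below this, the ratio is
#'   reported as `NA` with category `"undefined"`.
#' @return A `slope_ratio` list: `slope_a`, `slope_b`, `ratio`, `category`,
#'   `split_at`.
#' @export
slope_ratio <- function(fit, values = if (is.function(fit)) NULL else fit$x,
                        split = c("median", "range_midpoint"),
                        scale = c("log_hr", "hr"),
                        thresholds = c(0.8, 1.2),
                        degeneracy_floor = 1e-8) {
  split <- match.arg(split)
  scale <- match.arg(scale)
  if (is.null(values)) stop("covariate values required", call. = FALSE)
  lo <- min(values)
  hi <- max(values)
  mid <- if (split == "median") stats::median(values) else (lo + hi) / 2
  if (!(lo < mid && mid < hi)) {
    stop("degenerate covariate values: split point not interior", call. = FALSE)
  }
  eta <- if (is.function(fit)) {
    v <- fit(c(lo, mid, hi))
    v - v[1]
  } else {
    predict(fit, newx = c(lo, mid, hi), reference = lo)
  }
  y <- if (scale == "hr") exp(eta) else eta
  slope_a <- (y[2] - y[1]) / (mid - lo)
  slope_b <- (y[3] - y[2]) / (hi - mid)
  if (abs(slope_b) < degeneracy_floor) {
    ratio <- NA_real_
    category <- "undefined"
  } else {
    ratio <- slope_a / slope_b
    category <- if (ratio > thresholds[2]) "supralinear"
    else if (ratio < thresholds[1]) "sublinear"
    else "linear"
  }
  structure(list(slope_a = slope_a, slope_b = slope_b, ratio = ratio,
                 category = category, split_at = mid, scale = scale),
            class = "slope_ratio")
}

#' @export
print.slope_ratio <- function(x, ...) {
  cat(sprintf("Slope-ratio test (%s scale): A = %.5g, B = %.5g, ratio = %.4g -> %s\n",
              x$scale, x$slope_a, x$slope_b, x$ratio, x$category))
  invisible(x)
}

#' AIC-difference test for nonlinearity
#'
#' @param aic_linear,aic_spline AIC of the linear and spline Cox fits on
#'   the same data and covariate.
#' @return List with `delta` (`aic_linear - aic_spline`) and `nonlinear`
#'   (`TRUE` iff `delta > 2`, strict).
#' @export
aic_test <- function(aic_linear, aic_spline) {
  stopifnot(is.finite(aic_linear), is.finite(aic_spline))
  delta <- aic_linear - aic_spline
  list(delta = delta, nonlinear = delta > 2)
}

#' Percent change in slope ratio relative to a reference fit
#'
#' @param ratio_error Slope ratio from an error-contaminated fit (a
#'   `slope_ratio` object or a number).
#' @param ratio_reference Slope ratio from the no-error fit of the same
#'   cohort.
#' @param flag_threshold Percent change at or above which the replicate is
#'   flagged as shifted in the supralinear direction (default +20).
#' @return List with `percent_change` and `supralinear_shift`.
#' @export
relative_slope_change <- function(ratio_error, ratio_reference,
                                  flag_threshold = 20) {
  re <- if (inherits(ratio_error, "slope_ratio")) ratio_error$ratio else ratio_error
  rr <- if (inherits(ratio_reference, "slope_ratio")) ratio_reference$ratio else ratio_reference
  if (!is.finite(re) || !is.finite(rr) || rr == 0) {
    stop("slope ratios must be defined and the reference nonzero", call. = FALSE)
  }
  pc <- 100 * (re - rr) / rr
  list(percent_change = pc, supralinear_shift = pc >= flag_threshold)
}

#' Fit and assess the shape of a concentration-response function
#'
#' Fits linear and 2-df natural-spline Cox models to a simulated cohort on
#' a chosen covariate, then applies the slope-ratio and AIC-difference
#' tests to the spline fit.
#'
#' @param ds A `survival_dataset`.
#' @param x Fitting covariate per city (default the dataset's `pm_true`).
#' @param df Spline degrees of freedom.
#' @param ties Ties correction passed to [cox_grouped()].
#' @param ... Further arguments to [slope_ratio()].
#' @return A `shape_assessment` object: both fits, the slope-ratio result,
#'   the AIC verdict, and the fitted curve evaluator.
#' @examples
#' lt <- synthetic_life_table()
#' sched <- mortality_schedule(lt, 1940)
#' cfg <- cohort_config(n_cities = 30, city_size = 500, follow_up_years = 10)
#' set.seed(7)
#' pm <- sample_city_concentrations(30)
#' ds <- simulate_cohort(cfg, sched, linear_hazard(1.05), pm)
#' assess_shape(ds)
#' @export
assess_shape <- function(ds, x = ds$covariates$pm_true, df = 2,
                         ties = "efron", ...) {
  fit_lin <- cox_grouped(ds, x = x, term = "linear", ties = ties)
  fit_ns <- cox_grouped(ds, x = x, term = "ns", df = df, ties = ties)
  sr <- slope_ratio(fit_ns, values = x, ...)
  at <- aic_test(cox_aic(fit_lin), cox_aic(fit_ns))
  structure(list(fit_linear = fit_lin, fit_spline = fit_ns,
                 slope_ratio = sr,
                 aic_linear = cox_aic(fit_lin),
                 aic_spline = cox_aic(fit_ns),
                 aic_delta = at$delta,
                 aic_nonlinear = at$nonlinear,
                 x = x),
            class = "shape_assessment")
}

#' @export
print.shape_assessment <- function(x, ...) {
  cat("Concentration-response shape assessment\n")
  print(x$slope_ratio)
  cat(sprintf("AIC: linear %.2f, spline %.2f, difference %.3f -> %s\n",
              x$aic_linear, x$aic_spline, x$aic_delta,
              if (x$aic_nonlinear) "reject linearity" else "linear adequate"))
  invisible(x)
}

#' Plot the fitted hazard-ratio curve of a shape assessment
#'
#' @param x A `shape_assessment`.
#' @param n_grid Number of grid points.
#' @param ... Passed to [plot()].
#' @export
plot.shape_assessment <- function(x, n_grid = 200, ...) {
  g <- seq(min(x$x), max(x$x), length.out = n_grid)
  hr_ns <- exp(predict(x$fit_spline, newx = g, reference = min(x$x)))
  hr_lin <- exp(predict(x$fit_linear, newx = g, reference = min(x$x)))
  plot(g, hr_ns, type = "l", xlab = "exposure", ylab = "hazard ratio", ...)
  graphics::lines(g, hr_lin, lty = 2)
  graphics::abline(v = x$slope_ratio$split_at, col = "grey", lty = 3)
  graphics::legend("topleft", legend = c("spline", "linear"), lty = c(1, 2),
                   bty = "n")
  invisible(x)
}
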