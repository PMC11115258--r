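#' Concentration-response hazard models
#'
#' A hazard model maps a city's risk-factor value to a relative-risk
#' multiplier on the baseline annual death probability.  Two families:
#' log-linear (`RR = h^x`, i.e. linear on the log-hazard scale) and
#' supralinear, where the log hazard follows a logistic CDF of the
#' concentration above its minimum, rising steeply at low concentrations
#' and flattening at high ones.
#'
#' @name hazard_models
NULL

#' Log-linear hazard model
#'
#' @param h Hazard ratio per unit of the risk factor (> 0), e.g. 1.05 per
#'   ug/m3 of toxic PM2.5.
#' @return A `hazard_model` object.
#' @export
linear_hazard <- function(h) {
  if (!is.finite(h) || h <= 0) stop("hazard ratio must be positive", call. = FALSE)
  structure(list(type = "linear", h = h), class = "hazard_model")
}

#' Supralinear (logistic-CDF) hazard model
#'
#' Log relative risk at concentration `pm` is
#' `amplitude * (F((pm - pm_min)/scale) - F(0)) / (F((pm_max - pm_min)/scale) - F(0))`
#' with `F` the standard logistic CDF: anchored at RR = 1 at `pm_min` and
#' `exp(amplitude)` at `pm_max`, strictly increasing and concave between.
#' Smaller `scale` means stronger supralinearity; as `scale -> Inf` the
#' model converges to the log-linear model with the same endpoints.
#'
#' The default amplitude, `log(1.05) * (pm_max - pm_min)`, matches the
#' endpoint log relative risk of a log-linear model with hazard ratio 1.05
#' per ug/m3, so the supralinear family and its linear control are
#' comparable at the extremes of the concentration range.
#'
#' @param scale Logistic scale parameter in ug/m3 (> 0).
#' @param pm_min,pm_max Concentration range anchors (ug/m3).
#' @param amplitude Total log relative risk across the range (> 0).
#' @return A `hazard_model` object.
#' @export
supralinear_hazard <- function(scale, pm_min, pm_max,
                               amplitude = log(1.05) * (pm_max - pm_min)) {
  stopifnot(scale > 0, pm_max > pm_min, amplitude > 0)
  structure(list(type = "supralinear", scale = scale,
                 pm_min = pm_min, pm_max = pm_max, amplitude = amplitude),
            class = "hazard_model")
}

#' Relative-risk multiplier under a hazard model
#'
#' @param model A `hazard_model`.
#' @param x Risk-factor value(s): any non-negative value for the linear
#'   model; a concentration `>= pm_min` for the supralinear model.
#' @return Multiplier(s) applied to the baseline death probability.
#' @export
relative_risk <- function(model, x) {
  stopifnot(inherits(model, "hazard_model"))
  if (model$type == "linear") {
    if (any(x < 0)) stop("risk-factor values must be non-negative", call. = FALSE)
    return(exp(x * log(model$h)))
  }
  if (any(x < model$pm_min)) {
    stop("concentration below the model's pm_min", call. = FALSE)
  }
  Fz <- stats::plogis((x - model$pm_min) / model$scale)
  Ftop <- stats::plogis((model$pm_max - model$pm_min) / model$scale)
  exp(model$amplitude * (Fz - 0.5) / (Ftop - 0.5))
}

#' Annual death probability under a relative risk
#'
#' `min(1, B * multiplier)`; a warning is issued if clipping occurs (it
#' never does under the default simulation parameters).
#'
#' @param B Baseline annual death probability in \[0, 1\].
#' @param multiplier Relative-risk multiplier (> 0).
#' @return Probability in \[0, 1\].
#' @export
mortality_probability <- function(B, multiplier) {
  stopifnot(all(B >= 0 & B <= 1), all(multiplier > 0))
  p <- B * multiplier
  if (any(p > 1)) {
    warning(sprintf("%d death probabilities clipped at 1", sum(p > 1)))
    p <- pmin(1, p)
  }
  p
}
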