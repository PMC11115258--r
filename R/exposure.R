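#' City exposures: triangular PM2.5, scenario risk factors, measurement error
#'
#' Each hypothetical city gets a fixed true PM2.5 concentration drawn from a
#' triangular distribution (default min 5, mode 10, max 20 ug/m3, broadly
#' consistent with US cities).  Scenario risk factors are defined as a
#' percentage of the city's PM2.5, interpolated linearly in concentration
#' between the lowest- and highest-PM cities.  "Observed" PM2.5 adds
#' truncated-normal classical measurement error with a PM-dependent
#' standard deviation.
#'
#' @name exposure
NULL

#' Triangular distribution specification
#'
#' @param minimum,maximum,mode Distribution parameters in ug/m3, with
#'   `minimum <= mode <= maximum`.
#' @return A `triangular_spec` list.
#' @export
triangular_spec <- function(minimum = 5, maximum = 20, mode = 10) {
  if (!(minimum <= mode && mode <= maximum)) {
    stop("triangular spec requires minimum <= mode <= maximum", call. = FALSE)
  }
  structure(list(minimum = minimum, maximum = maximum, mode = mode),
            class = "triangular_spec")
}

# closed-form triangular quantile function
qtriangular <- function(p, spec) {
  a <- spec$minimum; b <- spec$maximum; m <- spec$mode
  if (a == b) return(rep(a, length(p)))
  fc <- (m - a) / (b - a)
  lower <- p <= fc
  out <- numeric(length(p))
  out[lower] <- a + sqrt(p[lower] * (b - a) * (m - a))
  out[!lower] <- b - sqrt((1 - p[!lower]) * (b - a) * (b - m))
  out
}

ptriangular <- function(q, spec) {
  a <- spec$minimum; b <- spec$maximum; m <- spec$mode
  ifelse(q <= a, 0,
         ifelse(q >= b, 1,
                ifelse(q <= m,
                       (q - a)^2 / ((b - a) * (m - a)),
                       1 - (b - q)^2 / ((b - a) * (b - m)))))
}

#' Draw city PM2.5 concentrations
#'
#' Inverse-CDF draws from a triangular distribution, returned sorted
#' ascending so that city 1 has the lowest and city `n_cities` the highest
#' concentration.  Concentrations are constant over follow-up time.
#'
#' @param n_cities Number of cities (>= 2).
#' @param spec A [triangular_spec()].
#' @return Numeric vector of length `n_cities`, sorted ascending, in ug/m3.
#' @export
sample_city_concentrations <- function(n_cities, spec = triangular_spec()) {
  stopifnot(inherits(spec, "triangular_spec"))
  if (n_cities < 2) stop("need at least 2 cities", call. = FALSE)
  sort(qtriangular(stats::runif(n_cities), spec))
}

#' Linear-in-concentration interpolation of city values
#'
#' Assigns each city a value interpolated linearly in its PM2.5
#' concentration between `v_low` at the lowest-PM city and `v_high` at
#' the highest-PM city.  Endpoints are exact.
#'
#' @param pm_true Sorted ascending city concentrations.
#' @param v_low,v_high Values (proportions or multipliers, > 0) at the
#'   lowest- and highest-PM cities.
#' @return Numeric vector of per-city values.
#' @export
interpolate_city_values <- function(pm_true, v_low, v_high) {
  stopifnot(v_low > 0, v_high > 0)
  if (is.unsorted(pm_true)) stop("pm_true must be sorted ascending", call. = FALSE)
  span <- pm_true[length(pm_true)] - pm_true[1]
  if (span == 0) {
    warning("all city concentrations equal; returning v_low everywhere")
    return(rep(v_low, length(pm_true)))
  }
  v_low + (v_high - v_low) * (pm_true - pm_true[1]) / span
}

#' Scenario risk-factor values
#'
#' In a toxic-fraction scenario the risk factor is the toxic portion of the
#' PM2.5 mass; in a proxy scenario it is some other exposure proportional
#' to PM2.5.  Both give `risk = v(pm) * pm` with `v` the interpolated
#' percentage; they differ only in whether `v` may exceed 1.
#'
#' @param pm_true Sorted city concentrations (ug/m3).
#' @param v_low,v_high Endpoint proportions (e.g. `0.70` for 70%).
#' @param kind `"toxic_fraction"` (requires `v <= 1`) or `"proxy"`.
#' @return Per-city risk-factor values (ug/m3 for toxic fraction;
#'   risk-factor units for proxy).
#' @export
risk_values <- function(pm_true, v_low, v_high,
                        kind = c("toxic_fraction", "proxy")) {
  kind <- match.arg(kind)
  if (kind == "toxic_fraction" && (v_low > 1 || v_high > 1)) {
    stop("toxic fractions cannot exceed 1", call. = FALSE)
  }
  v <- interpolate_city_values(pm_true, v_low, v_high)
  v * pm_true
}

#' Measurement-error specification
#'
#' Classical error: observed PM = true PM + e, with e zero-mean normal,
#' resampled until `|e| <= truncation` and observed PM >= 0.  Under the
#' positive-correlation pattern the error sd grows with concentration
#' (`sd = level * pm`, `level` in 0.05/0.10/0.20 for low/medium/high error).
#' Under the negative-correlation pattern the default construction is
#' `sd = pm / level` with divisor `level` in 15/20/23 (high/medium/low);
#' `negative_model = "inverse"` instead uses `sd = level / pm`, the reading
#' under which error is literally smaller where concentrations are higher.
#'
#' @param direction `"positive"` or `"negative"`.
#' @param level sd proportion (positive direction) or divisor/constant
#'   (negative direction).
#' @param truncation Absolute error bound in ug/m3 (default 5).
#' @param n_replicates Number of observed-PM replicate sets (default 100).
#' @param negative_model `"literal"` (`sd = pm/level`) or `"inverse"`
#'   (`sd = level/pm`); ignored for the positive direction.
#' @return A `measurement_error_spec` list.
#' @export
measurement_error_spec <- function(direction = c("positive", "negative"),
                                   level,
                                   truncation = 5,
                                   n_replicates = 100,
                                   negative_model = c("literal", "inverse")) {
  direction <- match.arg(direction)
  negative_model <- match.arg(negative_model)
  if (truncation <= 0) stop("truncation bound must be positive", call. = FALSE)
  if (n_replicates < 1) stop("need at least one replicate", call. = FALSE)
  if (level < 0) stop("error level must be non-negative", call. = FALSE)
  structure(list(direction = direction, level = level,
                 truncation = truncation, n_replicates = n_replicates,
                 negative_model = negative_model),
            class = "measurement_error_spec")
}

error_sd <- function(pm_true, spec) {
  if (spec$direction == "positive") {
    spec$level * pm_true
  } else if (spec$negative_model == "literal") {
    pm_true / spec$level
  } else {
    spec$level / pm_true
  }
}

#' Draw observed (error-contaminated) PM2.5 values
#'
#' One truncated-normal draw per city: rejection sampling until the error
#' is within `+/- truncation` and the observed concentration is
#' non-negative.  A zero sd returns the true values exactly.
#'
#' @param pm_true True concentrations (> 0).
#' @param spec A [measurement_error_spec()].
#' @return Observed concentrations, same length as `pm_true`.
#' @export
draw_observed_pm <- function(pm_true, spec) {
  stopifnot(inherits(spec, "measurement_error_spec"), all(pm_true > 0))
  sd <- error_sd(pm_true, spec)
  if (any(!is.finite(sd)) || any(sd < 0)) {
    stop("invalid (non-finite or negative) error sd", call. = FALSE)
  }
  e <- numeric(length(pm_true))
  todo <- sd > 0
  guard <- 0L
  while (any(todo)) {
    e[todo] <- stats::rnorm(sum(todo), 0, sd[todo])
    todo <- todo & (abs(e) > spec$truncation | pm_true + e < 0)
    guard <- guard + 1L
    if (guard > 10000L) stop("rejection sampling failed to terminate", call. = FALSE)
  }
  pm_true + e
}

#' Build a set of observed-PM replicates
#'
#' @param pm_true True city concentrations.
#' @param spec A [measurement_error_spec()].
#' @return A matrix with `spec$n_replicates` rows and `length(pm_true)`
#'   columns; row r is the r-th city-wise observed-PM vector.
#' @export
build_error_replicates <- function(pm_true, spec) {
  t(vapply(seq_len(spec$n_replicates),
           function(r) draw_observed_pm(pm_true, spec),
           numeric(length(pm_true))))
}
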