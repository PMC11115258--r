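#' Run configuration and reproducible seeding
#'
#' [cr_config()] collects every tunable constant of the simulation study
#' with its default, so experiment runners and the command-line script
#' share one validated configuration object.  [seed_for()] derives
#' deterministic, collision-resistant child seeds from a master seed so
#' any single scenario/replicate cell can be re-run in isolation.
#'
#' @name cli_io
NULL

#' Build a validated run configuration
#'
#' Unspecified fields take the study defaults: triangular PM (5, 20, 10)
#' ug/m3 over 100 cities of 10,000 men aged 60 starting in 2000 with
#' 20-year follow-up; hazard ratio 1.05 per unit for toxic-fraction and
#' proxy scenarios and \{1.005, 1.01, 1.02, 1.03\} for measurement-error
#' cohorts; slope-ratio thresholds 0.8/1.2; AIC-difference threshold 2;
#' error truncation +/- 5 ug/m3 with 100 replicate sets; 10 cohorts per
#' scenario.
#'
#' @param ... Named overrides of any default field.
#' @return A `cr_config` list.
#' @export
cr_config <- function(...) {
  defaults <- list(
    n_cities = 100L,
    city_size = 10000L,
    start_year = 2000L,
    baseline_age = 60L,
    sex = "male",
    follow_up_years = 20L,
    pm_min = 5, pm_max = 20, pm_mode = 10,
    hazard_ratio = 1.05,
    error_hazard_ratios = c(1.005, 1.01, 1.02, 1.03),
    supralinear_scales = c(1, 3, 5),
    n_cohorts = 10L,
    n_error_replicates = 100L,
    truncation = 5,
    positive_levels = c(0.05, 0.10, 0.20),
    negative_levels = c(15, 20, 23),
    negative_model = "literal",
    slope_thresholds = c(0.8, 1.2),
    aic_threshold = 2,
    shift_threshold = 20,
    split = "median",
    ties = "efron",
    spline_df = 2L,
    seed = 1L
  )
  overrides <- list(...)
  if (anyDuplicated(names(overrides))) {
    stop("duplicated config field(s): ",
         paste(unique(names(overrides)[duplicated(names(overrides))]),
               collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, overrides)
  validate_config(cfg)
}

#' Validate a raw configuration list
#'
#' Cross-field checks; returns the configuration classed `cr_config`.
#'
#' @param cfg A named list with the fields of [cr_config()].
#' @return The validated `cr_config`.
#' @export
validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_cities >= 2, city_size >= 1, follow_up_years >= 1,
              pm_min <= pm_mode, pm_mode <= pm_max,
              hazard_ratio > 0, all(error_hazard_ratios > 0),
              all(supralinear_scales > 0),
              n_cohorts >= 1, n_error_replicates >= 1, truncation > 0,
              length(slope_thresholds) == 2,
              slope_thresholds[1] < slope_thresholds[2],
              aic_threshold > 0, spline_df >= 2)
  })
  if (!cfg$split %in% c("median", "range_midpoint")) {
    stop("split must be 'median' or 'range_midpoint'", call. = FALSE)
  }
  if (!cfg$negative_model %in% c("literal", "inverse")) {
    stop("negative_model must be 'literal' or 'inverse'", call. = FALSE)
  }
  if (!cfg$ties %in% c("efron", "breslow")) {
    stop("ties must be 'efron' or 'breslow'", call. = FALSE)
  }
  structure(cfg, class = "cr_config")
}

#' Derive a child seed
#'
#' Deterministic Lehmer-style mixing of a master seed with scenario,
#' cohort-replicate and error-replicate indices, modulo 2^31 - 1 (all
#' arithmetic exact in doubles).  Distinct index tuples map to distinct
#' seeds across the study's grid sizes.
#'
#' @param master Master seed (non-negative integer).
#' @param scenario,cohort,error_rep Non-negative indices.
#' @return An integer seed in \[1, 2^31 - 2\] for [set.seed()].
#' @export
seed_for <- function(master, scenario = 0, cohort = 0, error_rep = 0) {
  p <- 2147483647 # 2^31 - 1 (prime)
  stopifnot(master >= 0, scenario >= 0, cohort >= 0, error_rep >= 0)
  h <- (master %% p)
  for (v in c(scenario, cohort, error_rep)) {
    # 48271 * p < 2^53, so the products are exact in double precision
    h <- (h * 48271 + (v %% p) * 7919 + 1) %% p
  }
  h <- (h * 48271 + 1) %% p
  as.integer(h %% (p - 2) + 1)
}
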