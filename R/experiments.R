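#' Experiment runners
#'
#' Orchestrate the four experiment families over their scenario grids:
#' true supralinearity (logistic-CDF hazards), toxic-fraction and
#' proxy-risk misspecification (linear hazards on a risk factor while the
#' Cox models are fitted on total PM), and classical measurement error
#' (linear hazards on true PM, refits on error-contaminated observed PM).
#' Each runner returns per-replicate detail plus a per-scenario summary of
#' supralinearity detections by the slope-ratio and AIC-difference tests.
#'
#' City PM concentrations are drawn once per family run (fixed geography);
#' cohort and error replicates get child seeds from [seed_for()], so any
#' cell is re-runnable in isolation.
#'
#' @name experiments
NULL

# family offsets for seed derivation
FAMILY_SUPRALINEAR <- 1000
FAMILY_TOXIC <- 2000
FAMILY_PROXY <- 3000
FAMILY_MEASERR <- 4000

#' Bundled scenario grids
#'
#' The 30 toxic-fraction and 44 proxy-risk scenario endpoint pairs, as
#' percentages of the city PM2.5 concentration at the lowest-PM
#' (`v_low_pct`) and highest-PM (`v_high_pct`) cities.  The relative
#' toxicity descriptor (`v_low/v_high`) is recomputed, not stored.
#'
#' @param kind `"toxic_fraction"` or `"proxy"`.
#' @return Data frame `scenario_id, v_low_pct, v_high_pct, relative_toxicity`.
#' @export
scenario_grid <- function(kind = c("toxic_fraction", "proxy")) {
  kind <- match.arg(kind)
  file <- if (kind == "toxic_fraction") "toxic_fraction_scenarios.csv"
          else "proxy_risk_scenarios.csv"
  path <- system.file("extdata", file, package = "crshape", mustWork = TRUE)
  g <- utils::read.csv(path)
  g$relative_toxicity <- round(g$v_low_pct / g$v_high_pct, 2)
  g
}

study_schedule <- function(config, life_table = NULL) {
  if (is.null(life_table)) life_table <- synthetic_life_table()
  mortality_schedule(life_table,
                     birth_year = config$start_year - config$baseline_age,
                     sex = config$sex)
}

study_cohort_config <- function(config) {
  cohort_config(n_cities = config$n_cities, city_size = config$city_size,
                start_year = config$start_year,
                baseline_age = config$baseline_age, sex = config$sex,
                follow_up_years = config$follow_up_years)
}

draw_study_pm <- function(config, family) {
  set.seed(seed_for(config$seed, family))
  sample_city_concentrations(
    config$n_cities,
    triangular_spec(config$pm_min, config$pm_max, config$pm_mode))
}

assess_with_config <- function(ds, x, config) {
  assess_shape(ds, x = x, df = config$spline_df, ties = config$ties,
               split = config$split, thresholds = config$slope_thresholds)
}

assessment_row <- function(a, scenario_label, rep, seed) {
  data.frame(scenario = scenario_label, rep = rep, seed = seed,
             slope_a = a$slope_ratio$slope_a,
             slope_b = a$slope_ratio$slope_b,
             ratio = a$slope_ratio$ratio,
             category = a$slope_ratio$category,
             aic_linear = a$aic_linear, aic_spline = a$aic_spline,
             aic_delta = a$aic_delta, aic_nonlinear = a$aic_nonlinear,
             stringsAsFactors = FALSE)
}

#' Summarise replicate detail into per-scenario detection counts
#'
#' @param detail Detail data frame from an experiment runner (one row per
#'   cohort replicate).
#' @return One row per scenario: replicates, supralinear counts by the
#'   slope-ratio test and by the AIC-difference test.
#' @export
summarize_results <- function(detail) {
  if (!nrow(detail)) stop("empty detail table", call. = FALSE)
  agg <- do.call(rbind, lapply(split(detail, detail$scenario), function(d) {
    data.frame(scenario = d$scenario[1],
               n = nrow(d),
               count_supralinear_slope = sum(d$category == "supralinear"),
               count_sublinear_slope = sum(d$category == "sublinear"),
               count_nonlinear_aic = sum(d$aic_nonlinear),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(match(agg$scenario, unique(detail$scenario))), , drop = FALSE]
}

#' Detecting true supralinearity
#'
#' Simulates cohorts whose mortality follows logistic-CDF supralinear
#' concentration-response functions (plus a log-linear control) with PM2.5
#' itself as the risk factor, and counts how often each shape test flags
#' supralinearity.
#'
#' @param config A [cr_config()].
#' @param scales Logistic scale parameters (ug/m3); `NA` denotes the
#'   linear control, appended by default.
#' @param life_table Optional `life_table`; defaults to the bundled
#'   Gompertz-Makeham baseline.
#' @return List with `detail` (one row per cohort) and `summary`.
#' @export
run_true_supralinearity <- function(config = cr_config(),
                                    scales = c(config$supralinear_scales, NA),
                                    life_table = NULL) {
  schedule <- study_schedule(config, life_table)
  ccfg <- study_cohort_config(config)
  pm <- draw_study_pm(config, FAMILY_SUPRALINEAR)
  rows <- list()
  for (si in seq_along(scales)) {
    sc <- scales[si]
    hz <- if (is.na(sc)) linear_hazard(config$hazard_ratio)
          else supralinear_hazard(sc, min(pm), max(pm))
    label <- if (is.na(sc)) "linear" else paste0("scale_", sc)
    for (rep in seq_len(config$n_cohorts)) {
      sd <- seed_for(config$seed, FAMILY_SUPRALINEAR + si, rep)
      set.seed(sd)
      ds <- simulate_cohort(ccfg, schedule, hz, pm)
      a <- assess_with_config(ds, pm, config)
      rows[[length(rows) + 1L]] <- assessment_row(a, label, rep, sd)
    }
  }
  detail <- do.call(rbind, rows)
  list(detail = detail, summary = summarize_results(detail), pm = pm)
}

run_misspecification <- function(config, grid, kind, family, life_table) {
  schedule <- study_schedule(config, life_table)
  ccfg <- study_cohort_config(config)
  pm <- draw_study_pm(config, family)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    v_low <- grid$v_low_pct[i] / 100
    v_high <- grid$v_high_pct[i] / 100
    risk <- risk_values(pm, v_low, v_high, kind = kind)
    hz <- linear_hazard(config$hazard_ratio)
    label <- sprintf("%d_%g_%g", grid$scenario_id[i],
                     grid$v_low_pct[i], grid$v_high_pct[i])
    for (rep in seq_len(config$n_cohorts)) {
      sd <- seed_for(config$seed, family + grid$scenario_id[i], rep)
      set.seed(sd)
      ds <- simulate_cohort(ccfg, schedule, hz, pm, risk_value = risk)
      # the misspecification under study: fit on total PM, not the risk factor
      a <- assess_with_config(ds, pm, config)
      rows[[length(rows) + 1L]] <- assessment_row(a, label, rep, sd)
    }
  }
  detail <- do.call(rbind, rows)
  summ <- summarize_results(detail)
  ids <- as.integer(sub("_.*", "", summ$scenario))
  summ <- cbind(summ[, "scenario", drop = FALSE],
                grid[match(ids, grid$scenario_id),
                     c("relative_toxicity", "v_low_pct", "v_high_pct")],
                summ[, -1, drop = FALSE])
  rownames(summ) <- NULL
  list(detail = detail, summary = summ, pm = pm)
}

#' Toxic-fraction misspecification experiment
#'
#' Mortality is driven by the toxic portion of PM2.5 mass (hazard ratio
#' 1.05 per ug/m3 of toxic PM) while the Cox models are fitted on total
#' PM2.5 — the misspecification that can fabricate apparent
#' supralinearity when the toxic fraction falls with total PM.
#'
#' @param config A [cr_config()].
#' @param grid Scenario grid (default the bundled 30 scenarios); subset
#'   rows to run fewer scenarios.
#' @param life_table Optional `life_table`.
#' @return List with `detail` and `summary` (including the recomputed
#'   relative-toxicity descriptor).
#' @export
run_toxic_fraction <- function(config = cr_config(),
                               grid = scenario_grid("toxic_fraction"),
                               life_table = NULL) {
  run_misspecification(config, grid, "toxic_fraction", FAMILY_TOXIC, life_table)
}

#' Proxy-risk misspecification experiment
#'
#' Mortality is driven by an unmeasured risk factor proportional to PM2.5
#' (possibly exceeding it) while the Cox models are fitted on total PM2.5.
#'
#' @inheritParams run_toxic_fraction
#' @export
run_proxy_risk <- function(config = cr_config(),
                           grid = scenario_grid("proxy"),
                           life_table = NULL) {
  run_misspecification(config, grid, "proxy", FAMILY_PROXY, life_table)
}

#' Measurement-error experiment
#'
#' For each hazard ratio, simulates one cohort with a linear hazard on
#' true PM, fits the no-error reference spline, then refits on
#' error-contaminated observed PM replicates and records the percent
#' change in slope ratio relative to the reference.  A change of at least
#' `config$shift_threshold` percent counts as a shift in the supralinear
#' direction.
#'
#' @param config A [cr_config()].
#' @param direction `"positive"` or `"negative"` error-PM correlation.
#' @param levels Error levels (sd proportions for positive; divisors or
#'   inverse constants for negative); defaults from `config`.
#' @param truncation Absolute error bound(s) in ug/m3.
#' @param hazard_ratios Cohort hazard ratios; defaults from `config`.
#' @param n_replicates Observed-PM replicate sets per (cohort, pattern).
#' @param life_table Optional `life_table`.
#' @return List with `detail` (one row per error replicate), `summary`
#'   (shift frequency per pattern x hazard ratio), and `reference` (the
#'   no-error slope ratios per cohort).
#' @export
run_measurement_error <- function(config = cr_config(),
                                  direction = "positive",
                                  levels = NULL,
                                  truncation = config$truncation,
                                  hazard_ratios = config$error_hazard_ratios,
                                  n_replicates = config$n_error_replicates,
                                  life_table = NULL) {
  if (is.null(levels)) {
    levels <- if (direction == "positive") config$positive_levels
              else config$negative_levels
  }
  schedule <- study_schedule(config, life_table)
  ccfg <- study_cohort_config(config)
  pm <- draw_study_pm(config, FAMILY_MEASERR)

  refs <- list()
  rows <- list()
  patterns <- expand.grid(level = levels, truncation = truncation)
  for (ih in seq_along(hazard_ratios)) {
    h <- hazard_ratios[ih]
    sd0 <- seed_for(config$seed, FAMILY_MEASERR + ih, 0)
    set.seed(sd0)
    ds <- simulate_cohort(ccfg, schedule, linear_hazard(h), pm)
    ref_fit <- cox_grouped(ds, x = pm, term = "ns", df = config$spline_df,
                           ties = config$ties)
    ref_sr <- slope_ratio(ref_fit, values = pm, split = config$split,
                          thresholds = config$slope_thresholds)
    refs[[ih]] <- data.frame(hazard_ratio = h, ratio_reference = ref_sr$ratio,
                             category = ref_sr$category)
    for (ip in seq_len(nrow(patterns))) {
      spec <- measurement_error_spec(direction = direction,
                                     level = patterns$level[ip],
                                     truncation = patterns$truncation[ip],
                                     n_replicates = n_replicates,
                                     negative_model = config$negative_model)
      for (r in seq_len(n_replicates)) {
        set.seed(seed_for(config$seed, FAMILY_MEASERR + ih, ip, r))
        obs <- draw_observed_pm(pm, spec)
        fit <- cox_grouped(ds, x = obs, term = "ns", df = config$spline_df,
                           ties = config$ties)
        sr <- slope_ratio(fit, values = obs, split = config$split,
                          thresholds = config$slope_thresholds)
        chg <- relative_slope_change(sr, ref_sr,
                                     flag_threshold = config$shift_threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          direction = direction, level = patterns$level[ip],
          truncation = patterns$truncation[ip], hazard_ratio = h, rep = r,
          ratio_reference = ref_sr$ratio, ratio = sr$ratio,
          percent_change = chg$percent_change,
          supralinear_shift = chg$supralinear_shift,
          stringsAsFactors = FALSE)
      }
    }
  }
  detail <- do.call(rbind, rows)
  key <- interaction(detail$level, detail$truncation, detail$hazard_ratio,
                     drop = TRUE)
  summary <- do.call(rbind, lapply(split(detail, key), function(d) {
    data.frame(direction = d$direction[1], level = d$level[1],
               truncation = d$truncation[1], hazard_ratio = d$hazard_ratio[1],
               n = nrow(d),
               shift_frequency_pct = 100 * mean(d$supralinear_shift),
               mean_percent_change = mean(d$percent_change))
  }))
  rownames(summary) <- NULL
  list(detail = detail,
       summary = summary[order(summary$level, summary$truncation,
                               summary$hazard_ratio), ],
       reference = do.call(rbind, refs), pm = pm)
}
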