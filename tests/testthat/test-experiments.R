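# Experiment-runner tests use a scaled-down configuration so each family
# runs in seconds; full-size behaviour is exercised in test-acceptance.R.
mini_config <- function(n_cities = 40, city_size = 400, follow_up_years = 10,
                        n_cohorts = 3L, n_error_replicates = 4L, seed = 5L,
                        ...) {
  cr_config(n_cities = n_cities, city_size = city_size,
            follow_up_years = follow_up_years, n_cohorts = n_cohorts,
            n_error_replicates = n_error_replicates, seed = seed, ...)
}

test_that("scenario grids load with recomputed relative toxicity", {
  tox <- scenario_grid("toxic_fraction")
  prox <- scenario_grid("proxy")
  expect_equal(nrow(tox), 30)
  expect_equal(nrow(prox), 44)
  expect_true(all(tox$v_low_pct <= 100 & tox$v_high_pct <= 100))
  expect_true(any(prox$v_low_pct > 100))
  expect_equal(tox$relative_toxicity, round(tox$v_low_pct / tox$v_high_pct, 2))
  # spot checks against the published descriptors
  expect_true(any(tox$relative_toxicity == 2.00 & tox$v_low_pct == 70))
  expect_true(any(prox$relative_toxicity == 1.50 & prox$v_low_pct == 150))
})

test_that("experiment runs are reproducible and order-independent in summary", {
  cfg <- mini_config()
  g <- scenario_grid("toxic_fraction")[c(4, 18), ]
  r1 <- run_toxic_fraction(cfg, grid = g)
  r2 <- run_toxic_fraction(cfg, grid = g)
  expect_identical(r1$detail, r2$detail)
  expect_identical(r1$summary, r2$summary)
  # permuting detail rows leaves counts unchanged
  perm <- r1$detail[sample(nrow(r1$detail)), ]
  expect_equal(summarize_results(perm)$count_supralinear_slope,
               r1$summary$count_supralinear_slope)
  expect_error(summarize_results(r1$detail[0, ]), "empty")
})

test_that("single-cell reruns reproduce the stored replicate", {
  cfg <- mini_config()
  g <- scenario_grid("toxic_fraction")[18, ] # 70/35
  r <- run_toxic_fraction(cfg, grid = g)
  row <- r$detail[r$detail$rep == 2, ]
  # re-run just that cohort from its recorded seed
  pm <- r$pm
  risk <- risk_values(pm, 0.70, 0.35, "toxic_fraction")
  set.seed(row$seed)
  ds <- simulate_cohort(
    cohort_config(n_cities = cfg$n_cities, city_size = cfg$city_size,
                  follow_up_years = cfg$follow_up_years),
    mortality_schedule(synthetic_life_table(), 1940),
    linear_hazard(1.05), pm, risk_value = risk)
  a <- assess_shape(ds, x = pm)
  expect_equal(a$slope_ratio$ratio, row$ratio)
  expect_equal(a$aic_delta, row$aic_delta)
})

test_that("supralinearity family orders detection by curvature", {
  cfg <- mini_config(city_size = 1500)
  r <- run_true_supralinearity(cfg, scales = c(3, NA))
  s <- r$summary
  expect_true(s$count_supralinear_slope[s$scenario == "scale_3"] >=
                s$count_supralinear_slope[s$scenario == "linear"])
  expect_true(all(r$detail$category[r$detail$scenario == "scale_3"] ==
                    "supralinear"))
})

test_that("measurement-error runner: zero error level changes nothing", {
  cfg <- mini_config()
  r <- run_measurement_error(cfg, direction = "positive", levels = 0,
                             hazard_ratios = 1.03, n_replicates = 3)
  expect_true(all(r$detail$percent_change == 0))
  expect_true(all(!r$detail$supralinear_shift))
  expect_equal(unique(r$detail$ratio), r$reference$ratio_reference)
})

test_that("measurement-error detail has full provenance and valid summary", {
  cfg <- mini_config()
  r <- run_measurement_error(cfg, direction = "negative", levels = c(15, 23),
                             hazard_ratios = c(1.02, 1.03), n_replicates = 3)
  expect_equal(nrow(r$detail), 2 * 2 * 3)
  expect_equal(nrow(r$summary), 4)
  expect_true(all(r$summary$shift_frequency_pct >= 0 &
                    r$summary$shift_frequency_pct <= 100))
  expect_true(all(r$summary$n == 3))
})

test_that("shorter follow-up increases shape-estimate variability", {
  cfg20 <- mini_config(n_cohorts = 6L)
  cfg1 <- mini_config(n_cohorts = 6L, follow_up_years = 1L)
  r20 <- run_true_supralinearity(cfg20, scales = NA)
  r1 <- run_true_supralinearity(cfg1, scales = NA)
  spread <- function(r) sd(r$detail$ratio)
  expect_gt(spread(r1), spread(r20))
})

test_that("pipeline shape conclusions are baseline-invariant for linear cohorts", {
  # two different life tables; a linear C-R cohort keeps slope ratio near 1
  cfg <- cr_config(n_cities = 100, city_size = 4000, follow_up_years = 20,
                   seed = 2L)
  lt_alt <- synthetic_life_table(a = 0.002, b = 0.02 * exp(-60 * 0.07),
                                 c = 0.07)
  pm <- local({set.seed(42); sample_city_concentrations(100)})
  ratios <- sapply(list(synthetic_life_table(), lt_alt), function(lt) {
    sched <- mortality_schedule(lt, 1940)
    set.seed(99)
    ds <- simulate_cohort(cohort_config(city_size = 4000), sched,
                          linear_hazard(1.05), pm)
    assess_shape(ds)$slope_ratio$ratio
  })
  expect_true(all(abs(ratios - 1) < 0.35))
})
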