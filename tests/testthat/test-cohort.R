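test_that("risk-set bookkeeping identities hold exactly", {
  fx <- small_cohort(n_cities = 15, city_size = 300, follow_up = 8)
  cn <- fx$ds$counts
  for (j in unique(cn$city)) {
    sub <- cn[cn$city == j, ]
    sub <- sub[order(sub$year), ]
    expect_true(all(sub$deaths <= sub$at_risk))
    expect_equal(sub$at_risk[-1], (sub$at_risk - sub$deaths)[-nrow(sub)])
    expect_equal(sub$at_risk[1], 300)
    expect_equal(sum(sub$deaths) + (300 - sum(sub$deaths)), 300)
  }
})

test_that("null-hazard death counts match the binomial law", {
  sched <- data.frame(age = 60:64, q = rep(0.02, 5))
  cfg <- cohort_config(n_cities = 2, city_size = 1e4, follow_up_years = 1)
  set.seed(4)
  ds <- simulate_cohort(cfg, sched, linear_hazard(1), pm_true = c(5, 20))
  d <- ds$counts$deaths
  expect_true(all(abs(d - 200) < 4 * sqrt(1e4 * 0.02 * 0.98)))
})

test_that("degenerate baselines behave: q = 0 and q = 1", {
  cfg <- cohort_config(n_cities = 3, city_size = 50, follow_up_years = 3)
  sched0 <- data.frame(age = 60:62, q = 0)
  ds0 <- simulate_cohort(cfg, sched0, linear_hazard(1.05), c(5, 10, 20))
  expect_equal(sum(ds0$counts$deaths), 0)
  expect_true(all(ds0$counts$at_risk == 50))

  sched1 <- data.frame(age = 60:62, q = 1)
  ds1 <- simulate_cohort(cfg, sched1, linear_hazard(1), c(5, 10, 20))
  expect_equal(sum(ds1$counts$deaths[ds1$counts$year == 1]), 150)
  expect_true(all(ds1$counts$at_risk[ds1$counts$year > 1] == 0))
})

test_that("grouped and per-individual engines agree distributionally", {
  # chi-square comparison of first-year death counts over 500 replicates
  sched <- data.frame(age = 60, q = 0.1)
  cfg <- cohort_config(n_cities = 1, city_size = 50, follow_up_years = 1)
  set.seed(8)
  d_grp <- replicate(500, sum(simulate_cohort(cfg, sched, linear_hazard(1),
                                              10)$counts$deaths))
  d_ind <- replicate(500, sum(simulate_cohort_individual(cfg, sched,
                                                         linear_hazard(1),
                                                         10)$counts$deaths))
  breaks <- c(-Inf, 2, 4, 6, 8, Inf)
  tab <- rbind(table(cut(d_grp, breaks)), table(cut(d_ind, breaks)))
  p <- suppressWarnings(chisq.test(tab))$p.value
  expect_gt(p, 0.01)
})

test_that("per-individual mode accounting: one record per person", {
  sched <- data.frame(age = 60:79, q = rep(0.05, 20))
  cfg <- cohort_config(n_cities = 2, city_size = 30, follow_up_years = 20)
  set.seed(2)
  ds <- simulate_cohort_individual(cfg, sched, linear_hazard(1.02), c(6, 18))
  ind <- expand_to_individuals(ds)
  expect_equal(nrow(ind), 60)
  expect_true(all(ind$time[ind$event == 0] == 20))
  # single individual, fair coin, one year
  cfg1 <- cohort_config(n_cities = 2, city_size = 1, follow_up_years = 1)
  sched1 <- data.frame(age = 60, q = 0.5)
  set.seed(3)
  ds1 <- simulate_cohort_individual(cfg1, sched1, linear_hazard(1), c(5, 20))
  expect_true(all(ds1$counts$deaths %in% 0:1))
})

test_that("expansion to individuals regroups to the original counts", {
  fx <- small_cohort(n_cities = 10, city_size = 100, follow_up = 6)
  ind <- expand_to_individuals(fx$ds)
  expect_equal(nrow(ind), 10 * 100)
  regroup <- aggregate(event ~ city + time, data = ind, FUN = sum)
  cn <- fx$ds$counts
  for (k in seq_len(nrow(regroup))) {
    orig <- cn$deaths[cn$city == regroup$city[k] & cn$year == regroup$time[k]]
    dexp <- regroup$event[k]
    if (regroup$time[k] < 6) expect_equal(dexp, orig)
  }
  # covariates carried through
  expect_true(all(c("pm_true", "risk_value") %in% names(ind)))
})

test_that("expected mortality is monotone in exposure under h > 1", {
  sched <- data.frame(age = 60:64, q = rep(0.05, 5))
  cfg <- cohort_config(n_cities = 5, city_size = 400, follow_up_years = 5)
  pm <- c(5, 8, 12, 16, 20)
  set.seed(10)
  cum <- rowMeans(replicate(25, {
    ds <- simulate_cohort(cfg, sched, linear_hazard(1.05), pm)
    tapply(ds$counts$deaths, ds$counts$city, sum)
  }))
  expect_true(all(diff(cum) > 0))
})

test_that("config mismatches are caught", {
  sched <- data.frame(age = 60:61, q = c(0.01, 0.012))
  cfg <- cohort_config(n_cities = 3, city_size = 10, follow_up_years = 2)
  expect_error(simulate_cohort(cfg, sched, linear_hazard(1.05), c(5, 10)),
               "one value per city")
  cfg4 <- cohort_config(n_cities = 2, city_size = 10, follow_up_years = 4)
  expect_error(simulate_cohort(cfg4, sched, linear_hazard(1.05), c(5, 10)),
               "does not cover ages")
})

test_that("expected cohort counts are the exact binomial means", {
  sched <- test_schedule()
  cfg <- cohort_config(n_cities = 4, city_size = 1000, follow_up_years = 3)
  pm <- c(5, 10, 15, 20)
  e <- expected_cohort(cfg, sched, linear_hazard(1.05), pm)
  q <- sched$q[match(60:62, sched$age)]
  rr <- 1.05^pm
  # year 1 closed form and the at-risk recursion
  expect_equal(e$counts$deaths[e$counts$year == 1], 1000 * q[1] * rr)
  for (t in 2:3) {
    prev <- e$counts[e$counts$year == t - 1, ]
    cur <- e$counts[e$counts$year == t, ]
    expect_equal(cur$at_risk, prev$at_risk - prev$deaths)
    expect_equal(cur$deaths, cur$at_risk * q[t] * rr)
  }
  # grouped simulation is unbiased around the expectation
  set.seed(77)
  sims <- replicate(400, sum(simulate_cohort(cfg, sched, linear_hazard(1.05),
                                             pm)$counts$deaths))
  mu <- sum(e$counts$deaths)
  expect_lt(abs(mean(sims) - mu), 4 * sd(sims) / sqrt(400))
})
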