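oracle_fit <- function(ds, formula_rhs, ties) {
  skip_if_not_installed("survival")
  ind <- expand_to_individuals(ds)
  f <- stats::as.formula(paste("survival::Surv(time, event) ~", formula_rhs))
  survival::coxph(f, data = ind, ties = ties)
}

test_that("grouped fitter agrees with survival::coxph on random instances", {
  for (seed in 1:3) {
    fx <- small_cohort(n_cities = 20, city_size = 50, follow_up = 5,
                       h = 1.06, seed = seed)
    for (ties in c("efron", "breslow")) {
      fit <- cox_grouped(fx$ds, term = "linear", ties = ties)
      ref <- oracle_fit(fx$ds, "pm_true", ties)
      expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
      expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
      expect_equal(cox_aic(fit), stats::AIC(ref), tolerance = 1e-6)
      expect_equal(unname(sqrt(diag(vcov(fit)))),
                   unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
    }
  }
})

test_that("spline fit matches coxph + splines::ns, including the log-HR curve", {
  fx <- small_cohort(n_cities = 25, city_size = 80, follow_up = 6, h = 1.08,
                     seed = 4)
  fit <- cox_grouped(fx$ds, term = "ns", df = 2)
  ref <- oracle_fit(fx$ds, "splines::ns(pm_true, df = 2)", "efron")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
  grid <- seq(min(fx$pm), max(fx$pm), length.out = 11)
  ours <- predict(fit, newx = grid, reference = min(fx$pm))
  b <- splines::ns(fx$pm, df = 2)
  eta <- predict(b, grid) %*% coef(ref)
  theirs <- drop(eta - drop(predict(b, min(fx$pm)) %*% coef(ref)))
  expect_equal(ours, theirs, tolerance = 1e-6)
})

test_that("partial likelihood is location invariant and rescales exactly", {
  fx <- small_cohort(seed = 5)
  f0 <- cox_grouped(fx$ds, x = fx$pm, term = "linear")
  f_shift <- cox_grouped(fx$ds, x = fx$pm + 7, term = "linear")
  f_scale <- cox_grouped(fx$ds, x = fx$pm * 2, term = "linear")
  expect_equal(f0$loglik, f_shift$loglik, tolerance = 1e-8)
  expect_equal(coef(f0), coef(f_shift), tolerance = 1e-8)
  expect_equal(f0$loglik, f_scale$loglik, tolerance = 1e-8)
  expect_equal(unname(coef(f0)), unname(coef(f_scale)) * 2, tolerance = 1e-8)
})

test_that("score at the optimum is below tolerance and nesting holds", {
  for (seed in c(2, 6)) {
    fx <- small_cohort(n_cities = 30, city_size = 100, follow_up = 8,
                       seed = seed)
    lin <- cox_grouped(fx$ds, term = "linear")
    ns2 <- cox_grouped(fx$ds, term = "ns")
    expect_lt(max(abs(lin$score)), 1e-7)
    expect_lt(max(abs(ns2$score)), 1e-7)
    # natural-spline space contains linear functions
    expect_gte(ns2$loglik, lin$loglik - 1e-8)
    expect_gte(cox_aic(ns2), cox_aic(lin) - 2 - 1e-8)
  }
})

test_that("degenerate inputs are rejected or flagged, not silent", {
  fx <- small_cohort(n_cities = 5, city_size = 40, follow_up = 3, seed = 7)
  expect_error(cox_grouped(fx$ds, x = rep(3, 5), term = "linear"),
               "zero-variance")
  # no deaths
  sched0 <- data.frame(age = 60:62, q = 0)
  cfg <- cohort_config(n_cities = 3, city_size = 10, follow_up_years = 3)
  ds0 <- simulate_cohort(cfg, sched0, linear_hazard(1), c(5, 10, 20))
  expect_error(cox_grouped(ds0, term = "linear"), "no deaths")
  # monotone likelihood: all deaths in the single highest-exposure city
  ds <- fx$ds
  ds$counts$deaths <- ifelse(ds$counts$city == 5, ds$counts$deaths, 0L)
  ds$counts$at_risk <- ave(ds$counts$deaths, ds$counts$city,
                           FUN = function(d) 40L - c(0L, cumsum(d)[-length(d)]))
  expect_warning(fit <- cox_grouped(ds, x = c(1, 2, 3, 4, 5),
                                    term = "linear"),
                 "monotone|did not converge")
  expect_false(fit$converged)
  expect_error(cox_aic(fit), "unconverged")
})

test_that("AIC formula and unconverged-fit guard", {
  fx <- small_cohort(seed = 8)
  fit <- cox_grouped(fx$ds, term = "ns")
  expect_equal(cox_aic(fit), -2 * fit$loglik + 2 * 2)
  broken <- fit
  broken$converged <- FALSE
  expect_error(cox_aic(broken), "unconverged")
})

test_that("natural spline basis contains linear functions and has df columns", {
  set.seed(9)
  x <- sample_city_concentrations(100)
  b <- ns_basis(x, df = 2)
  expect_equal(dim(unclass(b)), c(100, 2))
  # least-squares reconstruction of x from {1, basis}
  r <- residuals(lm(x ~ eval_basis(b, x)))
  expect_lt(max(abs(r)), 1e-10)
  # boundary evaluation finite and independent columns
  bb <- eval_basis(b, range(x))
  expect_true(all(is.finite(bb)))
  expect_equal(qr(eval_basis(b, x))$rank, 2)
  expect_error(eval_basis(b, max(x) + 1), "outside")
  expect_error(ns_basis(c(1, 1, 2)), "3 distinct")
})

test_that("prediction is anchored at the reference and exact for linear fits", {
  fx <- small_cohort(seed = 10)
  lin <- cox_grouped(fx$ds, term = "linear")
  g <- seq(min(fx$pm), max(fx$pm), length.out = 7)
  expect_equal(predict(lin, newx = min(fx$pm)), 0)
  expect_equal(predict(lin, newx = g),
               unname(coef(lin)) * (g - min(fx$pm)))
  ns2 <- cox_grouped(fx$ds, term = "ns")
  expect_equal(predict(ns2, newx = min(fx$pm)), 0)
  expect_error(predict(ns2, newx = max(fx$pm) + 0.5), "outside")
})
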