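# Shared fixtures: a small default schedule and quick cohort builders.

test_schedule <- function() {
  mortality_schedule(synthetic_life_table(), birth_year = 1940, sex = "male")
}

small_cohort <- function(n_cities = 20, city_size = 200, follow_up = 5,
                         h = 1.05, seed = 1, pm = NULL) {
  set.seed(seed)
  if (is.null(pm)) pm <- sample_city_concentrations(n_cities)
  cfg <- cohort_config(n_cities = n_cities, city_size = city_size,
                       follow_up_years = follow_up)
  ds <- simulate_cohort(cfg, test_schedule(), linear_hazard(h), pm)
  list(ds = ds, pm = pm, cfg = cfg)
}

# full study-size cohort under a given hazard (used by acceptance tests)
study_cohort <- function(hazard, pm, seed) {
  set.seed(seed)
  simulate_cohort(cohort_config(), test_schedule(), hazard, pm)
}
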