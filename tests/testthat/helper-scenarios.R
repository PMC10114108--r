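# shared fixtures: estimator-validation configs run on complete panels
# (no missingness / attrition) so estimation error is isolated from
# imputation; imputation has its own designed scenarios

no_miss <- list(rate = 0, mar = c(employment = 0, age = 0))

clean_cfg <- function(n, waves, seed, ...) {
  sim_config(n_individuals = n, n_waves = waves, seed = seed,
             missingness = no_miss, attrition_rate = 0, ...)
}

# panel -> analysis table with poverty re-derived from income
make_tab <- function(cfg) {
  build_analysis_table(derive_poverty(generate_panel(cfg)))
}

esp_default <- exposure_spec(numerator = "wave_f")

# small deterministic person-wave fixture for derivation tests
toy_panel <- function() {
  data.frame(
    person_id = rep(1:2, each = 3), household_id = rep(1:2, each = 3),
    wave = rep(1:3, 2),
    income = c(1000, 1100, 1200, 2000, 2100, 2200),
    housing_costs = c(300, 300, 300, 500, 500, 500),
    n_adults = 1L, n_children = 0L,
    gender = rep(0:1, each = 3), ethnicity = 0L, education = 2L,
    employment = 1L, benefits = 0L, tenure = 1L, marital = 0L,
    region = 1L, age = rep(c(30L, 31L, 32L), 2),
    sf12_pcs = 50, sf12_mcs = 50,
    ghq_score = c(2L, 5L, 1L, 0L, 4L, 3L),
    ghq_case = c(0L, 1L, 0L, 0L, 1L, 0L))
}
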