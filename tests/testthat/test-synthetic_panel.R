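test_that("identical config and seed give identical panels and missingness", {
  cfg <- sim_config(200, 4, seed = 5)
  p1 <- generate_panel(cfg)
  p2 <- generate_panel(cfg)
  expect_identical(p1, p2)
  m1 <- impose_missingness(p1, cfg)
  m2 <- impose_missingness(p2, cfg)
  expect_identical(m1$panel, m2$panel)
  expect_identical(m1$miss_ind, m2$miss_ind)
  # a different seed perturbs the draws
  p3 <- generate_panel(sim_config(200, 4, seed = 6))
  expect_false(identical(p1$income, p3$income))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(0, 5), "n_individuals")
  expect_error(sim_config(100, 1), "n_waves")
  expect_error(sim_config(100, 5, missingness = list(rate = 1.2)), "rate")
  expect_error(sim_config(100, 5, attrition_rate = -0.1), "attrition")
  expect_error(sim_config(100, 5, randomize_exposure = 2), "randomize")
})

test_that("default calibrated scenario has realistic prevalences", {
  p <- generate_panel(sim_config(20000, 6, seed = 42))
  expect_gt(mean(p$a), 0.18); expect_lt(mean(p$a), 0.27)
  expect_gt(mean(p$ghq_case), 0.16); expect_lt(mean(p$ghq_case), 0.24)
})

test_that("randomized exposure: crude association matches oracle truth", {
  # all confounding paths severed and exposure assigned at random, so the
  # unadjusted person-wave association is the causal risk difference
  cfg <- scenario_config("no_confounding", n_individuals = 100000, seed = 31,
                         n_waves = 3, randomize_exposure = 0.5,
                         missingness = no_miss, attrition_rate = 0)
  truth <- compute_oracle_truth(cfg, n_mc = 100000)
  p <- generate_panel(cfg)
  p <- p[p$wave >= 2 & p$age >= 25 & p$age <= 64, ]
  crude <- 100 * (mean(p$ghq_case[p$a == 1]) - mean(p$ghq_case[p$a == 0]))
  emp_se <- 100 * sqrt(var(p$ghq_case[p$a == 1]) / sum(p$a == 1) +
                       var(p$ghq_case[p$a == 0]) / sum(p$a == 0))
  expect_lt(abs(crude - truth$true_rd),
            3 * sqrt(emp_se^2 + truth$mc_se^2))
})

test_that("oracle null: zero exposure effect gives null risk difference", {
  cfg <- scenario_config("null_effect", n_individuals = 10, seed = 7,
                         n_waves = 4)
  truth <- compute_oracle_truth(cfg, n_mc = 50000)
  # the per-row counterfactual contrast is exactly zero under the null,
  # so the bound holds with equality
  expect_lte(abs(truth$true_rd), 3 * truth$mc_se)
  # OR within the mc_se-equivalent band around 1
  p0 <- 0.2
  or_band <- 3 * truth$mc_se / 100 / (p0 * (1 - p0))
  expect_lt(abs(log(truth$true_or)), or_band + 0.02)
})

test_that("oracle matches the closed-form logistic contrast without confounding", {
  b <- -1.2; beta <- 0.5
  cfg <- sim_config(10, 2, seed = 3, exposure_effect = beta,
                    baseline_cmd_logit = b, y_lag_effect = 0,
                    a_lag_effect = 0, selection_effect = 0,
                    confounder_effects = list(
                      employment = 0, employment_lag = 0, benefits = 0,
                      tenure = 0, marital = 0, children = 0, education = 0,
                      physical = 0, mcs = 0, age = 0, age2 = 0),
                    missingness = no_miss, attrition_rate = 0)
  truth <- compute_oracle_truth(cfg, n_mc = 20000)
  closed <- 100 * (plogis(b + beta) - plogis(b))
  expect_lt(abs(truth$true_rd - closed), 1e-8 + 3 * truth$mc_se)
})

test_that("oracle risk difference is monotone in the exposure effect", {
  t1 <- compute_oracle_truth(sim_config(10, 4, seed = 11,
                                        exposure_effect = 0.2), 20000)
  t2 <- compute_oracle_truth(sim_config(10, 4, seed = 11,
                                        exposure_effect = 0.4), 20000)
  expect_gt(t2$true_rd, t1$true_rd)
})

test_that("missingness imposition honours rate zero, target rate and MAR", {
  cfg0 <- sim_config(500, 4, seed = 9, missingness = list(rate = 0),
                     attrition_rate = 0)
  p <- generate_panel(cfg0)
  out0 <- impose_missingness(p, cfg0)
  expect_identical(out0$panel, p)

  cfg1 <- sim_config(1500, 4, seed = 9,
                     missingness = list(rate = 0.1,
                                        mar = c(employment = -0.6)),
                     attrition_rate = 0)
  p1 <- generate_panel(cfg1)
  out1 <- impose_missingness(p1, cfg1)
  frac <- mean(as.matrix(out1$miss_ind))  # > 60000 cells
  expect_gt(frac, 0.09); expect_lt(frac, 0.11)

  # MAR: unemployed rows lose more cells than employed rows
  mi <- rowMeans(as.matrix(out1$miss_ind))
  emp <- out1$panel$employment
  r_unemp <- mean(mi[!is.na(emp) & emp == 0])
  r_emp <- mean(mi[!is.na(emp) & emp == 1])
  expect_gt(r_unemp, r_emp)
  expect_gt(stats::prop.test(
    x = c(sum(mi[!is.na(emp) & emp == 0] * ncol(out1$miss_ind)),
          sum(mi[!is.na(emp) & emp == 1] * ncol(out1$miss_ind))),
    n = c(sum(!is.na(emp) & emp == 0), sum(!is.na(emp) & emp == 1)) *
      ncol(out1$miss_ind))$p.value < 0.01, 0)
})

test_that("attrition is monotone: no person reappears after dropping out", {
  cfg <- sim_config(800, 6, seed = 13, missingness = list(rate = 0),
                    attrition_rate = 0.15)
  out <- impose_missingness(generate_panel(cfg), cfg)
  waves <- tapply(out$panel$wave, out$panel$person_id,
                  function(w) all(diff(sort(w)) == 1) && min(w) == 1)
  expect_true(all(waves))
})

test_that("scenario configs load from key-value files", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("scenario: strong_selection", "n_individuals: 150",
               "n_waves: 3", "seed: 21"), path)
  cfg <- sim_config_from_file(path)
  expect_equal(cfg$selection_effect, -1.2)
  expect_equal(cfg$n_individuals, 150L)
  expect_identical(generate_panel(cfg),
                   generate_panel(scenario_config("strong_selection",
                                                  n_individuals = 150,
                                                  seed = 21, n_waves = 3)))
  path2 <- tempfile(fileext = ".yaml")
  writeLines(c("n_individuals: 80", "n_waves: 2", "seed: 4",
               "exposure_effect: 0.3"), path2)
  expect_equal(sim_config_from_file(path2)$exposure_effect, 0.3)
})

test_that("panel CSV round-trips with empty cells for missing values", {
  cfg <- sim_config(50, 3, seed = 2)
  out <- impose_missingness(generate_panel(cfg), cfg)
  path <- tempfile(fileext = ".csv")
  write_panel(out$panel, path)
  back <- read_panel(path)
  expect_equal(nrow(back), nrow(out$panel))
  expect_equal(is.na(back$income), is.na(out$panel$income))
  expect_equal(back$income, out$panel$income, tolerance = 1e-9)
})
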