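test_that("population attributable fraction formula and sign convention", {
  expect_equal(compute_paf(25, 20), 20)
  expect_equal(compute_paf(20, 20), 0)
  expect_equal(compute_paf(20, 21), -5)  # protective exposure allowed
  expect_error(compute_paf(0, 10), "positive")
})

test_that("null exposure coefficient gives exact null identities", {
  # balanced design where P(Y | A, W) is identical across A within W, so
  # the MLE exposure coefficient is exactly zero
  cell <- function(w, a, y1, n) {
    data.frame(w = w, a = a, ghq_case = rep(c(1L, 0L), c(y1, n - y1)))
  }
  d <- rbind(cell(0, 0, 2, 10), cell(0, 1, 2, 10),
             cell(1, 0, 5, 10), cell(1, 1, 5, 10))
  d$person_id <- seq_len(nrow(d))
  ws <- list(sw = rep(1, nrow(d)))
  est <- estimate_effect(d, ws, outcome_spec("w"), "a", "ghq_case")
  expect_equal(est$rd, 0, tolerance = 1e-7)
  expect_equal(est$or_, 1, tolerance = 1e-7)
  expect_equal(est$paf, 0, tolerance = 1e-7)
})

test_that("saturated model reproduces the contingency-table standardization", {
  # 8-cell fixture: counts by (W, A) with differing outcome risks
  mk <- function(w, a, y1, n) data.frame(
    w = w, a = a, ghq_case = rep(c(1L, 0L), c(y1, n - y1)))
  d <- rbind(mk(0, 0, 3, 20), mk(0, 1, 8, 16),
             mk(1, 0, 6, 12), mk(1, 1, 9, 12))
  d$person_id <- seq_len(nrow(d))
  # independent oracle: empirical cell risks standardized over P(W)
  p <- function(w, a) {
    s <- d[d$w == w & d$a == a, ]
    mean(s$ghq_case)
  }
  pw1 <- mean(d$w)
  oracle_rd <- 100 * ((p(0, 1) - p(0, 0)) * (1 - pw1) +
                      (p(1, 1) - p(1, 0)) * pw1)
  est <- estimate_effect(d, list(sw = rep(1, nrow(d))),
                         outcome_spec(c("w", "a:w")), "a", "ghq_case")
  expect_equal(est$rd, oracle_rd, tolerance = 1e-6)
  # PAF identity is exact on every emitted estimate
  expect_equal(est$paf,
               100 * (est$prev_total - est$prev_unexposed) / est$prev_total)
})

test_that("bootstrap is deterministic and matches the analytic SE", {
  # single-wave table, intercept-only weights, outcome model a alone:
  # the estimator reduces to a difference in proportions whose analytic
  # SE is known
  set.seed(301)
  n <- 2000
  a <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-1 + 0.4 * a))
  tab <- data.frame(person_id = 1:n, wave = 2L, a = a, ghq_case = y,
                    wave_f = factor(2))
  esp <- exposure_spec(denominator = "1", numerator = "1")
  osp <- outcome_spec(character(0))
  b1 <- bootstrap_estimate(tab, esp, osp, n_replicates = 200, seed = 9)
  b2 <- bootstrap_estimate(tab, esp, osp, n_replicates = 200, seed = 9)
  expect_identical(b1$ci, b2$ci)
  p1 <- mean(y[a == 1]); p0 <- mean(y[a == 0])
  analytic <- 100 * sqrt(p1 * (1 - p1) / sum(a) + p0 * (1 - p0) / sum(1 - a))
  expect_lt(abs(b1$se$rd - analytic) / analytic, 0.15)
  expect_lt(b1$ci$rd[1], b1$rd); expect_gt(b1$ci$rd[2], b1$rd)
})

test_that("transition estimation recomputes weights on the restricted sample", {
  tab <- make_tab(clean_cfg(3000, 4, seed = 33))
  into <- estimate_transitions(tab, "into", esp_default)
  outof <- estimate_transitions(tab, "outof", esp_default)
  expect_equal(into$estimand, "into")
  expect_equal(outof$estimand, "outof")
  expect_equal(into$n_observations + outof$n_observations, nrow(tab))
  # degenerate input: nobody ever in poverty
  never <- tab[tab$a_lag == 0, ]
  never$a <- 0L
  expect_error(estimate_transitions(never, "outof", esp_default), "empty")
})

test_that("stratified estimation dichotomizes working age at 40/41", {
  tab <- make_tab(clean_cfg(2500, 4, seed = 34))
  res <- estimate_stratified(tab, "age_group", esp_default)
  expect_setequal(names(res), c("younger", "older"))
  tt <- tab; tt$age_group <- ifelse(tt$age <= 40, "younger", "older")
  expect_equal(sum(tt$age_group == "younger" & tt$age == 40) > 0, TRUE)
  expect_true(all(tt$age_group[tt$age == 41] == "older"))
  n_y <- res$younger$n_observations
  expect_equal(n_y, sum(tt$age_group == "younger"))
})

test_that("gender-specific effects are recovered by stratification", {
  hits <- 0
  for (r in 1:8) {
    cfg <- clean_cfg(3000, 4, seed = 400 + r, exposure_effect = 0.05,
                     exposure_effect_gender = 0.5)
    res <- estimate_stratified(make_tab(cfg), "gender", esp_default)
    hits <- hits + (res[["1"]]$rd > res[["0"]]$rd)
  }
  expect_gte(hits, 7)  # women's larger true effect detected
})

test_that("homogeneous effects give mutually compatible stratum estimates", {
  tab <- make_tab(clean_cfg(4000, 4, seed = 41))
  res <- estimate_stratified(tab, "gender", esp_default)
  lor <- sapply(res, function(e) log(e$or_))
  se <- sapply(res, function(e) sqrt(e$outcome_fit$vcov_cluster["a", "a"]))
  expect_lt(abs(lor[1] - lor[2]), 3 * sqrt(sum(se^2)))
})

test_that("tidy results follow the documented schema", {
  tab <- make_tab(clean_cfg(1200, 3, seed = 43))
  est <- estimate_effect(tab, compute_stabilized_weights(tab, esp_default))
  td <- tidy_estimates(est, "binary", "all")
  expect_equal(td$estimand, "binary")
  expect_true(all(c("rd", "or_", "prev_unexposed", "prev_total", "paf",
                    "n_individuals", "n_observations") %in% names(td)))
  expect_equal(td$n_observations, nrow(tab))
})
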