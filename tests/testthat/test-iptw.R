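test_that("logistic fit: closed forms, clustering, and recovery", {
  set.seed(101)
  d <- data.frame(y = rbinom(500, 1, 0.3), person_id = 1:500)
  f <- fit_logistic(y ~ 1, d)
  expect_equal(unname(f$coef), qlogis(mean(d$y)), tolerance = 1e-6)

  # one cluster per row: cluster-robust equals heteroscedasticity-robust
  # up to the finite-cluster factor G/(G-1)
  d$x <- rnorm(500)
  f2 <- fit_logistic(y ~ x, d, cluster = seq_len(nrow(d)))
  hc <- sandwich::vcovHC(f2$fit, type = "HC0")
  g <- nrow(d)
  expect_equal(unname(f2$vcov_cluster), unname(hc) * g / (g - 1),
               tolerance = 1e-8)

  # coefficient recovery at n = 20000
  set.seed(102)
  n <- 20000
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  eta <- -1 + 0.7 * x1 - 0.5 * x2
  dd <- data.frame(y = rbinom(n, 1, plogis(eta)), x1 = x1, x2 = x2)
  f3 <- fit_logistic(y ~ x1 + x2, dd)
  se <- sqrt(diag(f3$vcov))
  expect_lt(abs(f3$coef[["x1"]] - 0.7), 3 * se[["x1"]])
  expect_lt(abs(f3$coef[["x2"]] + 0.5), 3 * se[["x2"]])
})

test_that("separation and collinearity are surfaced", {
  d <- data.frame(y = c(rep(0, 20), rep(1, 20)),
                  x = c(rep(0, 20), rep(1, 20)))
  expect_error(fit_logistic(y ~ x, d), "separation")
  set.seed(5)
  d2 <- data.frame(y = rbinom(50, 1, 0.5), x = rnorm(50))
  d2$x_dup <- d2$x
  expect_warning(fit_logistic(y ~ x + x_dup, d2), "collinear")
})

test_that("stabilized weights: identities and diagnostics", {
  tab <- make_tab(clean_cfg(2000, 4, seed = 23))
  # numerator spec == denominator spec: all weights exactly 1
  same <- exposure_spec(denominator = default_adjustment_set(),
                        numerator = default_adjustment_set())
  ws_same <- compute_stabilized_weights(tab, same)
  expect_equal(ws_same$sw, rep(1, nrow(tab)), tolerance = 1e-12)

  ws <- compute_stabilized_weights(tab, esp_default)
  # ratio identity row by row
  expect_equal(ws$sw, ws$p_num / ws$p_den, tolerance = 1e-12)
  expect_true(all(ws$sw > 0 & is.finite(ws$sw)))
  # mean stabilized weight near one under a well-specified model
  tab5 <- make_tab(clean_cfg(5000, 5, seed = 24))
  ws5 <- compute_stabilized_weights(tab5, esp_default)
  expect_gt(ws5$summary[["mean"]], 0.95)
  expect_lt(ws5$summary[["mean"]], 1.05)
})

test_that("truncation clamps the tails without reordering interior weights", {
  tab <- make_tab(clean_cfg(1500, 4, seed = 25))
  esp_t <- exposure_spec(numerator = "wave_f", truncation = c(0.05, 0.95))
  ws <- compute_stabilized_weights(tab, esp_default)
  wst <- compute_stabilized_weights(tab, esp_t)
  expect_lt(max(wst$sw), max(ws$sw) + 1e-12)
  expect_gt(min(wst$sw), min(ws$sw) - 1e-12)
  keep <- !wst$truncated
  expect_equal(order(ws$sw[keep]), order(wst$sw[keep]))
  expect_true(any(wst$truncated))
})

test_that("positivity violations raise an error listing rows", {
  tab <- make_tab(clean_cfg(800, 3, seed = 26))
  strict <- exposure_spec(numerator = "wave_f", positivity_floor = 0.9)
  expect_error(compute_stabilized_weights(tab, strict), "positivity")
})

test_that("standardized mean differences: closed forms and edge cases", {
  expect_equal(compute_smd(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 0, 0, 0)), 0)
  expect_equal(compute_smd(c(0, 1, 2, -1, 0, 1), c(1, 1, 1, 0, 0, 0)), 1)
  # symmetry under group swap
  x <- c(0.3, 1.5, 2, 0.1, 0.9, 2.2); g <- c(1, 1, 0, 0, 1, 0)
  expect_equal(compute_smd(x, g), -compute_smd(x, 1 - g))
  # zero pooled variance
  expect_equal(compute_smd(rep(5, 6), g), 0)
  expect_equal(compute_smd(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 0, 0, 0)), Inf)
  expect_error(compute_smd(1:3, c(1, 1, 1)), "non-empty")
})

test_that("weighted SMD equals the integer-weight replication oracle", {
  x <- c(1.2, -0.5, 3.1, 0.0, 2.2, -1.7)
  g <- c(1, 1, 1, 0, 0, 0)
  w <- c(2, 1, 1, 1, 1, 2)
  # independent oracle: expand each row weight-many times, unweighted SMD
  xe <- rep(x, w); ge <- rep(g, w)
  m1 <- mean(xe[ge == 1]); m0 <- mean(xe[ge == 0])
  oracle <- (m1 - m0) / sqrt((var(xe[ge == 1]) + var(xe[ge == 0])) / 2)
  expect_equal(compute_smd(x, g, w), oracle, tolerance = 1e-12)
})

test_that("balance table: unit weights reproduce the unweighted column", {
  tab <- make_tab(clean_cfg(800, 3, seed = 27))
  unit <- list(sw = rep(1, nrow(tab)))
  bal <- balance_table(tab, unit, esp_default)
  expect_equal(bal$smd_weighted, bal$smd_unweighted, tolerance = 1e-12)
  expect_true(all(c("covariate", "smd_unweighted", "smd_weighted",
                    "flag_0.1", "flag_0.2") %in% names(bal)))
  # categorical covariates expand to one indicator per level
  expect_true(all(c("education=1", "education=2", "education=3") %in%
                  bal$covariate))
  p <- plot_balance(bal)
  expect_s3_class(p, "ggplot")
})
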