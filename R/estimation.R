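# Double-robust estimation of poverty effects ---------------------------------
#
# The outcome model is a weighted pooled logistic regression with the same
# confounder set as the exposure-model denominator (double robust: either
# model correct suffices). The marginal risk difference comes from
# g-computation standardization: predict every row with exposure forced to 1
# and to 0, average with the stabilized weights, difference. The odds ratio
# is the exposure coefficient of the weighted adjusted model (a conditional
# OR; the marginal counterfactual prevalences are also reported so the
# divergence is visible). The population attributable fraction uses the
# standard prevalence identity.

#' Outcome model specification
#'
#' @param covariates confounder terms of the outcome model; by design the
#'   same set as the exposure-model denominator.
#' @return An `outcome_spec` list.
#' @export
outcome_spec <- function(covariates = default_adjustment_set()) {
  structure(list(covariates = covariates), class = "outcome_spec")
}

#' Population attributable fraction
#'
#' 100 * (prev_total - prev_unexposed) / prev_total, in percent. Negative
#' values indicate a protective exposure.
#'
#' @param prev_total outcome prevalence in the total population (%).
#' @param prev_unexposed counterfactual prevalence with exposure removed (%).
#' @return PAF in percent.
#' @export
compute_paf <- function(prev_total, prev_unexposed) {
  if (any(prev_total <= 0)) stop("prev_total must be positive", call. = FALSE)
  100 * (prev_total - prev_unexposed) / prev_total
}

#' Double-robust effect estimate (point estimates only)
#'
#' @param analysis_table the estimation table.
#' @param weight_set stabilized weights from [compute_stabilized_weights()].
#' @param spec an [outcome_spec()].
#' @param exposure_col binary exposure column.
#' @param outcome_col binary outcome column.
#' @param compute_vcov FALSE skips covariance matrices (inner bootstrap).
#' @return List of class `effect_estimate`: `rd` (percentage points),
#'   `or_`, `prev_unexposed`, `prev_exposed`, `prev_total` (all %), `paf`
#'   (%), `n_individuals`, `n_observations`, and the fitted outcome model.
#' @export
estimate_effect <- function(analysis_table, weight_set,
                            spec = outcome_spec(),
                            exposure_col = "a", outcome_col = "ghq_case",
                            compute_vcov = TRUE) {
  terms <- c(exposure_col, spec$covariates)
  fml <- .build_formula(outcome_col, terms)
  fit <- fit_logistic(fml, analysis_table, weights = weight_set$sw,
                      cluster = analysis_table$person_id,
                      compute_vcov = compute_vcov)
  sw <- weight_set$sw
  d1 <- analysis_table; d1[[exposure_col]] <- 1L; d1$.w <- sw
  d0 <- analysis_table; d0[[exposure_col]] <- 0L; d0$.w <- sw
  p1 <- stats::predict(fit$fit, newdata = d1, type = "response")
  p0 <- stats::predict(fit$fit, newdata = d0, type = "response")
  pobs <- stats::fitted(fit$fit)
  m1 <- sum(sw * p1) / sum(sw)
  m0 <- sum(sw * p0) / sum(sw)
  mt <- sum(sw * pobs) / sum(sw)
  rd <- 100 * (m1 - m0)
  prev_unexposed <- 100 * m0
  prev_total <- 100 * mt
  structure(list(
    rd = rd,
    or_ = unname(exp(fit$coef[exposure_col])),
    prev_unexposed = prev_unexposed,
    prev_exposed = 100 * m1,
    prev_total = prev_total,
    paf = compute_paf(prev_total, prev_unexposed),
    n_individuals = length(unique(analysis_table$person_id)),
    n_observations = nrow(analysis_table),
    outcome_fit = fit),
    class = "effect_estimate")
}

#' Person-level cluster bootstrap of the full weighting + estimation pipeline
#'
#' Resamples persons (all their rows) with replacement, recomputes the
#' stabilized weights and the effect estimate on each replicate, and
#' attaches standard errors and confidence intervals to the point estimates
#' from the original table. Replicates failing (e.g. separation) are
#' dropped and counted; more than 10% failures is an error.
#'
#' @param analysis_table the estimation table.
#' @param exposure_sp an [exposure_spec()].
#' @param outcome_sp an [outcome_spec()].
#' @param n_replicates bootstrap replicates (>= 100 for reported CIs).
#' @param seed integer seed.
#' @param ci "normal" (point +- 1.96 se, matching bootstrapped standard
#'   errors) or "percentile".
#' @param exposure_col,outcome_col column names.
#' @return An `effect_estimate` augmented with `se`, `ci` (named list per
#'   quantity), `n_replicates_used`, `n_replicates_failed`.
#' @export
bootstrap_estimate <- function(analysis_table, exposure_sp = exposure_spec(),
                               outcome_sp = outcome_spec(),
                               n_replicates = 500L, seed = 1L,
                               ci = c("normal", "percentile"),
                               exposure_col = "a", outcome_col = "ghq_case") {
  ci <- match.arg(ci)
  if (n_replicates < 100L)
    warning("fewer than 100 bootstrap replicates; CIs not reliable")
  point <- estimate_effect(
    analysis_table, compute_stabilized_weights(analysis_table, exposure_sp,
                                               exposure_col),
    outcome_sp, exposure_col, outcome_col, compute_vcov = FALSE)
  ids <- unique(analysis_table$person_id)
  rows_by_id <- split(seq_len(nrow(analysis_table)), analysis_table$person_id)
  rows_by_id <- rows_by_id[as.character(ids)]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  quantities <- c("rd", "or_", "prev_unexposed", "prev_total", "paf")
  reps <- matrix(NA_real_, n_replicates, length(quantities),
                 dimnames = list(NULL, quantities))
  failed <- 0L
  # replicate path: the same weight + outcome models on pre-built model
  # matrices (row resampling leaves the design columns unchanged)
  a_obs <- analysis_table[[exposure_col]]
  y_obs <- analysis_table[[outcome_col]]
  X_den <- stats::model.matrix(.build_formula(exposure_col,
                                              exposure_sp$denominator),
                               analysis_table)
  X_num <- stats::model.matrix(.build_formula(exposure_col,
                                              exposure_sp$numerator),
                               analysis_table)
  X_out <- stats::model.matrix(.build_formula(outcome_col,
                                              c(exposure_col,
                                                outcome_sp$covariates)),
                               analysis_table)
  a_col <- match(exposure_col, colnames(X_out))
  # weighted-logistic IRLS on normal equations (Cholesky) -- much faster
  # than the QR path for the many small refits of the bootstrap loop;
  # singular or non-converged fits fall back to stats::glm.fit
  fit_p <- function(X, y, w = NULL, start = NULL) {
    if (is.null(w)) w <- rep(1, length(y))
    beta <- tryCatch({
      b <- if (is.null(start)) numeric(ncol(X)) else start
      for (i in seq_len(30L)) {
        eta <- drop(X %*% b)
        mu <- expit(eta)
        v <- pmax(mu * (1 - mu), 1e-10)
        wk <- w * v
        z <- eta + (y - mu) / v
        bn <- drop(solve(crossprod(X, X * wk), crossprod(X, wk * z)))
        if (max(abs(bn - b)) < 1e-9) { b <- bn; break }
        b <- bn
      }
      b
    }, error = function(e) {
      f <- suppressWarnings(stats::glm.fit(X, y, weights = w,
                                           family = stats::quasibinomial()))
      ifelse(is.na(f$coefficients), 0, f$coefficients)
    })
    list(beta = beta, p = expit(drop(X %*% beta)))
  }
  # full-sample fits warm-start each replicate's IRLS
  s_den <- fit_p(X_den, a_obs)$beta
  s_num <- fit_p(X_num, a_obs)$beta
  s_out <- NULL
  for (b in seq_len(n_replicates)) {
    take <- sample(length(ids), replace = TRUE)
    idx <- unlist(rows_by_id[take], use.names = FALSE)
    est <- tryCatch({
      a <- a_obs[idx]
      den <- fit_p(X_den[idx, , drop = FALSE], a, start = s_den)
      num <- fit_p(X_num[idx, , drop = FALSE], a, start = s_num)
      p_den <- ifelse(a == 1, den$p, 1 - den$p)
      if (any(p_den < exposure_sp$positivity_floor))
        stop("positivity violation in replicate")
      sw <- ifelse(a == 1, num$p, 1 - num$p) / p_den
      if (!is.null(exposure_sp$truncation)) {
        q <- stats::quantile(sw, exposure_sp$truncation)
        sw <- pmin(pmax(sw, q[1]), q[2])
      }
      Xb <- X_out[idx, , drop = FALSE]
      out <- fit_p(Xb, y_obs[idx], sw, start = s_out)
      s_out <- out$beta
      X1 <- Xb; X1[, a_col] <- 1
      X0 <- Xb; X0[, a_col] <- 0
      m1 <- sum(sw * expit(drop(X1 %*% out$beta))) / sum(sw)
      m0 <- sum(sw * expit(drop(X0 %*% out$beta))) / sum(sw)
      mt <- sum(sw * out$p) / sum(sw)
      c(rd = 100 * (m1 - m0), or_ = unname(exp(out$beta[a_col])),
        prev_unexposed = 100 * m0, prev_total = 100 * mt,
        paf = compute_paf(100 * mt, 100 * m0))
    }, error = function(e) NULL)
    if (is.null(est)) { failed <- failed + 1L; next }
    reps[b, ] <- est[quantities]
  }
  if (failed > 0.1 * n_replicates)
    stop("more than 10% of bootstrap replicates failed (", failed, "/",
         n_replicates, ")", call. = FALSE)
  se <- apply(reps, 2, stats::sd, na.rm = TRUE)
  cis <- lapply(quantities, function(q) {
    if (ci == "normal") {
      unname(point[[q]] + c(-1.96, 1.96) * se[[q]])
    } else {
      unname(stats::quantile(reps[, q], c(0.025, 0.975), na.rm = TRUE))
    }
  })
  names(cis) <- quantities
  point$se <- as.list(se)
  point$ci <- cis
  point$n_replicates_used <- n_replicates - failed
  point$n_replicates_failed <- failed
  point$replicates <- reps
  point
}

#' Transition-specific effects (moves into / out of poverty)
#'
#' Restricts the table per the transition estimand, recomputes stabilized
#' weights on the restricted sample (the lagged-exposure term, constant by
#' construction, is removed from both weight models), and estimates as in
#' [estimate_effect()] with the transition exposure.
#'
#' @param analysis_table full analysis table.
#' @param estimand "into" or "outof".
#' @param exposure_sp,outcome_sp specifications (lagged exposure removed
#'   automatically).
#' @param bootstrap NULL or a list(n_replicates=, seed=) to add bootstrap
#'   uncertainty.
#' @param outcome_col binary outcome column.
#' @return An `effect_estimate` tagged with the estimand.
#' @export
estimate_transitions <- function(analysis_table,
                                 estimand = c("into", "outof"),
                                 exposure_sp = exposure_spec(),
                                 outcome_sp = outcome_spec(),
                                 bootstrap = NULL,
                                 outcome_col = "ghq_case") {
  estimand <- match.arg(estimand)
  tab <- derive_transitions(analysis_table, estimand)
  if (nrow(tab) == 0)
    stop("empty restricted table for estimand '", estimand, "'",
         call. = FALSE)
  den <- setdiff(exposure_sp$denominator, "a_lag")
  num <- setdiff(exposure_sp$numerator, "a_lag")
  if (!length(num)) num <- "1"
  esp <- exposure_spec(denominator = den, numerator = intersect(num, c(den, "1")),
                       truncation = exposure_sp$truncation,
                       positivity_floor = exposure_sp$positivity_floor)
  osp <- outcome_spec(setdiff(outcome_sp$covariates, "a_lag"))
  est <- if (is.null(bootstrap)) {
    estimate_effect(tab, compute_stabilized_weights(tab, esp, "exposure"),
                    osp, "exposure", outcome_col)
  } else {
    bootstrap_estimate(tab, esp, osp,
                       n_replicates = bootstrap$n_replicates %||% 500L,
                       seed = bootstrap$seed %||% 1L,
                       exposure_col = "exposure", outcome_col = outcome_col)
  }
  est$estimand <- estimand
  est
}

#' Stratified effects with weights refit within stratum
#'
#' Stratifiers: gender, education, or age group (younger 25-40 vs older
#' 41-64, assigned per row at time t). The stratifier is removed from both
#' the weight and outcome covariate sets for its own run.
#'
#' @param analysis_table full analysis table.
#' @param stratifier "gender", "education" or "age_group".
#' @param exposure_sp,outcome_sp specifications.
#' @param bootstrap NULL or list(n_replicates=, seed=).
#' @param exposure_col,outcome_col column names.
#' @return Named list of `effect_estimate`, one per stratum; strata whose
#'   fit fails (e.g. a single exposure level) carry the error condition.
#' @export
estimate_stratified <- function(analysis_table,
                                stratifier = c("gender", "education",
                                               "age_group"),
                                exposure_sp = exposure_spec(),
                                outcome_sp = outcome_spec(),
                                bootstrap = NULL,
                                exposure_col = "a",
                                outcome_col = "ghq_case") {
  stratifier <- match.arg(stratifier)
  tab <- analysis_table
  drop_term <- switch(stratifier,
                      gender = "gender",
                      education = "factor(education)",
                      age_group = NULL)
  if (stratifier == "age_group")
    tab$age_group <- ifelse(tab$age <= 40, "younger", "older")
  strata <- split(tab, tab[[stratifier]])
  esp <- exposure_spec(denominator = setdiff(exposure_sp$denominator, drop_term),
                       numerator = setdiff(exposure_sp$numerator, drop_term),
                       truncation = exposure_sp$truncation,
                       positivity_floor = exposure_sp$positivity_floor)
  osp <- outcome_spec(setdiff(outcome_sp$covariates, drop_term))
  lapply(strata, function(s) {
    tryCatch({
      est <- if (is.null(bootstrap)) {
        estimate_effect(s, compute_stabilized_weights(s, esp, exposure_col),
                        osp, exposure_col, outcome_col)
      } else {
        bootstrap_estimate(s, esp, osp,
                           n_replicates = bootstrap$n_replicates %||% 500L,
                           seed = bootstrap$seed %||% 1L,
                           exposure_col = exposure_col,
                           outcome_col = outcome_col)
      }
      est$stratum <- stratifier
      est
    }, error = function(e) e)
  })
}

#' Tidy one or more effect estimates into the results CSV schema
#'
#' @param estimates a single `effect_estimate` or a named list of them.
#' @param estimand,stratum labels for the rows.
#' @return data.frame: estimand, stratum, rd, rd_se, rd_lo, rd_hi, or_,
#'   or_lo, or_hi, prev_unexposed, prev_total, paf, paf_se, paf_lo, paf_hi,
#'   n_individuals, n_observations.
#' @export
tidy_estimates <- function(estimates, estimand = "binary", stratum = "all") {
  one <- function(e, est_tag, str_tag) {
    if (inherits(e, "error"))
      return(data.frame(estimand = est_tag, stratum = str_tag, rd = NA_real_,
                        rd_se = NA_real_, rd_lo = NA_real_, rd_hi = NA_real_,
                        or_ = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
                        prev_unexposed = NA_real_, prev_total = NA_real_,
                        paf = NA_real_, paf_se = NA_real_, paf_lo = NA_real_,
                        paf_hi = NA_real_, n_individuals = NA_integer_,
                        n_observations = NA_integer_))
    g <- function(x, i) if (is.null(x)) NA_real_ else unname(x[[i]])
    data.frame(
      estimand = e$estimand %||% est_tag, stratum = str_tag,
      rd = e$rd, rd_se = g(e$se, "rd"),
      rd_lo = if (is.null(e$ci)) NA_real_ else e$ci$rd[1],
      rd_hi = if (is.null(e$ci)) NA_real_ else e$ci$rd[2],
      or_ = e$or_,
      or_lo = if (is.null(e$ci)) NA_real_ else e$ci$or_[1],
      or_hi = if (is.null(e$ci)) NA_real_ else e$ci$or_[2],
      prev_unexposed = e$prev_unexposed, prev_total = e$prev_total,
      paf = e$paf, paf_se = g(e$se, "paf"),
      paf_lo = if (is.null(e$ci)) NA_real_ else e$ci$paf[1],
      paf_hi = if (is.null(e$ci)) NA_real_ else e$ci$paf[2],
      n_individuals = e$n_individuals, n_observations = e$n_observations)
  }
  if (inherits(estimates, "effect_estimate"))
    return(one(estimates, estimand, stratum))
  do.call(rbind, Map(one, estimates, estimand,
                     if (length(stratum) == 1) names(estimates) else stratum))
}
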