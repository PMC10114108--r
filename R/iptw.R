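# Stabilized IPTW: exposure model, weights, balance diagnostics ---------------

#' Default confounder adjustment set
#'
#' The denominator covariates of the exposure model and the covariates of
#' the double-robust outcome model: time-invariant confounders (gender,
#' ethnicity, education), lagged time-varying confounders (benefits,
#' tenure, marital status, children, region, SF-12 physical and mental
#' components, prior caseness, prior poverty), employment at t and t-1, age
#' and age squared, and the survey-wave marker.
#'
#' @param drop character vector of terms to omit (e.g. a stratifier, or a
#'   deliberately omitted confounder in robustness checks).
#' @return Character vector of model terms.
#' @export
default_adjustment_set <- function(drop = character()) {
  setdiff(c("gender", "ethnicity", "factor(education)", "employment",
            "employment_lag", "benefits_lag", "tenure_lag", "marital_lag",
            "n_children_lag", "factor(region_lag)", "sf12_pcs_lag",
            "sf12_mcs_lag", "y_lag", "a_lag", "age", "age2", "wave_f"),
          drop)
}

#' Exposure model specification for stabilized weights
#'
#' @param denominator character terms for the denominator model (full
#'   confounder set).
#' @param numerator character terms for the stabilization numerator
#'   (default: the wave marker only, keeping the marginal time trend in
#'   the numerator while leaving every confounder -- including prior
#'   exposure -- to be balanced by the weights).
#' @param truncation NULL or a length-2 percentile pair in [0, 1], e.g.
#'   c(0.01, 0.99), at which weights are clamped.
#' @param positivity_floor lowest admissible fitted probability of the
#'   observed exposure; smaller values raise a positivity error.
#' @return An `exposure_spec` list.
#' @export
exposure_spec <- function(denominator = default_adjustment_set(),
                          numerator = "wave_f",
                          truncation = NULL,
                          positivity_floor = 1e-6) {
  if (!all(setdiff(numerator, "1") %in% denominator))
    stop("numerator covariates must be a subset of denominator covariates",
         call. = FALSE)
  if (!is.null(truncation) &&
      (length(truncation) != 2 || any(truncation < 0) || any(truncation > 1)))
    stop("truncation must be a percentile pair in [0, 1]", call. = FALSE)
  structure(list(denominator = denominator, numerator = numerator,
                 truncation = truncation,
                 positivity_floor = positivity_floor),
            class = "exposure_spec")
}

#' Pooled logistic regression with cluster-robust covariance
#'
#' Maximum-likelihood logistic fit with optional case weights, returning
#' both the model-based and the cluster-robust (sandwich) covariance
#' grouped by person. Collinear columns are dropped with a warning; perfect
#' separation raises an error naming the worst covariate.
#'
#' @param formula model formula.
#' @param data data.frame.
#' @param weights optional non-negative case weights.
#' @param cluster optional cluster ids (person); defaults to one cluster
#'   per row, in which case the cluster-robust covariance is the
#'   heteroscedasticity-robust one.
#' @param compute_vcov FALSE skips both covariance matrices (used in inner
#'   bootstrap loops where only fitted values are needed).
#' @return List: `fit` (glm), `coef`, `vcov` (model-based),
#'   `vcov_cluster`, `dropped` (aliased columns removed).
#' @export
fit_logistic <- function(formula, data, weights = NULL, cluster = NULL,
                         compute_vcov = TRUE) {
  data$.w <- if (is.null(weights)) rep(1, nrow(data)) else weights
  fit <- suppressWarnings(
    stats::glm(formula, data = data, family = stats::quasibinomial(),
               weights = .w, model = compute_vcov))
  cf <- stats::coef(fit)
  dropped <- names(cf)[is.na(cf)]
  if (length(dropped)) {
    warning("dropping collinear columns: ", paste(dropped, collapse = ", "))
  }
  p <- stats::fitted(fit)
  if (!fit$converged || any(p < 1e-10) || any(p > 1 - 1e-10)) {
    keep <- !is.na(cf)
    worst <- names(cf)[keep][which.max(abs(cf[keep]))]
    stop("possible perfect separation in logistic fit (covariate: ",
         worst, ")", call. = FALSE)
  }
  vc <- NULL; vcc <- NULL
  if (compute_vcov) {
    vc <- stats::vcov(fit)
    cl <- if (is.null(cluster)) seq_len(nrow(data)) else cluster
    vcc <- sandwich::vcovCL(fit, cluster = cl, type = "HC0")
  }
  list(fit = fit, coef = cf[!is.na(cf)], vcov = vc, vcov_cluster = vcc,
       dropped = dropped)
}

.build_formula <- function(response, terms) {
  stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")),
                    env = parent.frame())
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' Fits the denominator exposure model (full confounder set) and the
#' numerator model (stabilization), both on the same rows, and returns per
#' row sw = P_num(A = a_obs) / P_den(A = a_obs). Under a correctly
#' specified denominator model the weights average close to 1.
#'
#' @param analysis_table table from [build_analysis_table()] (or a
#'   transition restriction with an `exposure` column).
#' @param spec an [exposure_spec()].
#' @param exposure_col column holding the binary exposure (default "a").
#' @return A `weight_set` list: `sw`, `p_num`, `p_den`, `summary`,
#'   `truncated` (logical flags), plus the two fitted models.
#' @export
compute_stabilized_weights <- function(analysis_table, spec = exposure_spec(),
                                       exposure_col = "a") {
  a <- analysis_table[[exposure_col]]
  den <- fit_logistic(.build_formula(exposure_col, spec$denominator),
                      analysis_table, compute_vcov = FALSE)
  num <- fit_logistic(.build_formula(exposure_col, spec$numerator),
                      analysis_table, compute_vcov = FALSE)
  p_den1 <- stats::fitted(den$fit)
  p_num1 <- stats::fitted(num$fit)
  p_den <- ifelse(a == 1, p_den1, 1 - p_den1)
  p_num <- ifelse(a == 1, p_num1, 1 - p_num1)
  viol <- which(p_den < spec$positivity_floor)
  if (length(viol))
    stop("positivity violation: fitted probability of observed exposure ",
         "below ", spec$positivity_floor, " for rows ",
         paste(utils::head(viol, 10), collapse = ", "), call. = FALSE)
  sw <- p_num / p_den
  truncated <- rep(FALSE, length(sw))
  if (!is.null(spec$truncation)) {
    q <- stats::quantile(sw, spec$truncation)
    truncated <- sw < q[1] | sw > q[2]
    sw <- pmin(pmax(sw, q[1]), q[2])
  }
  structure(list(
    sw = sw, p_num = p_num, p_den = p_den, truncated = truncated,
    summary = c(mean = mean(sw), sd = stats::sd(sw), min = min(sw),
                max = max(sw),
                p01 = unname(stats::quantile(sw, 0.01)),
                p99 = unname(stats::quantile(sw, 0.99))),
    denominator_fit = den, numerator_fit = num, spec = spec),
    class = "weight_set")
}

#' Standardized mean difference between exposure groups
#'
#' (mean1 - mean0) / sqrt((s1^2 + s0^2)/2). The weighted version uses
#' frequency-weight means and variances, so with integer weights it equals
#' the SMD of the sample in which each row is replicated weight-many times.
#' Binary covariates are treated as 0/1 numerics. If the pooled variance is
#' zero the SMD is 0 for equal means and signed infinity otherwise.
#'
#' @param x covariate values.
#' @param group 0/1 exposure indicator.
#' @param w optional non-negative weights.
#' @return The SMD (exposed minus unexposed).
#' @export
compute_smd <- function(x, group, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  ok <- !is.na(x) & !is.na(group)
  x <- x[ok]; group <- group[ok]; w <- w[ok]
  if (!any(group == 1) || !any(group == 0))
    stop("both exposure groups must be non-empty", call. = FALSE)
  s1 <- weighted_stats(x[group == 1], w[group == 1])
  s0 <- weighted_stats(x[group == 0], w[group == 0])
  pooled <- sqrt((s1$var + s0$var) / 2)
  dm <- s1$mean - s0$mean
  if (!is.finite(pooled) || pooled == 0) {
    if (abs(dm) < .Machine$double.eps^0.5) return(0)
    return(sign(dm) * Inf)
  }
  dm / pooled
}

# covariates reported in the balance table, with indicator expansion for
# categoricals
.balance_covariates <- function(analysis_table, terms) {
  out <- list()
  for (tm in terms) {
    if (tm == "wave_f") next
    v <- sub("^factor\\((.*)\\)$", "\\1", tm)
    x <- analysis_table[[v]]
    if (is.null(x)) next
    if (grepl("^factor\\(", tm) || is.factor(x)) {
      lev <- sort(unique(x))
      for (l in lev) out[[paste0(v, "=", l)]] <- as.numeric(x == l)
    } else {
      out[[v]] <- as.numeric(x)
    }
  }
  out
}

#' Covariate balance before and after weighting
#'
#' One row per (indicator-expanded) adjustment-set covariate with the
#' unweighted and weighted SMD between exposure groups, flagged at
#' |SMD| >= 0.1 (non-negligible) and >= 0.2 (imbalanced).
#'
#' @param analysis_table the estimation table.
#' @param weight_set from [compute_stabilized_weights()].
#' @param spec the [exposure_spec()] whose denominator set defines the
#'   covariates to tabulate.
#' @param exposure_col binary exposure column.
#' @return data.frame of class `balance_table`: covariate, smd_unweighted,
#'   smd_weighted, flag_0.1, flag_0.2.
#' @export
balance_table <- function(analysis_table, weight_set,
                          spec = exposure_spec(), exposure_col = "a") {
  a <- analysis_table[[exposure_col]]
  covs <- .balance_covariates(analysis_table, spec$denominator)
  rows <- lapply(names(covs), function(nm) {
    x <- covs[[nm]]
    data.frame(covariate = nm,
               smd_unweighted = compute_smd(x, a),
               smd_weighted = compute_smd(x, a, weight_set$sw))
  })
  out <- do.call(rbind, rows)
  out$flag_0.1 <- abs(out$smd_weighted) >= 0.1
  out$flag_0.2 <- abs(out$smd_weighted) >= 0.2
  class(out) <- c("balance_table", "data.frame")
  out
}

#' Love plot of covariate balance
#'
#' @param bal a [balance_table()].
#' @return A ggplot object (dotted guides at +-0.1).
#' @export
plot_balance <- function(bal) {
  long <- rbind(
    data.frame(covariate = bal$covariate, smd = bal$smd_unweighted,
               weighted = "Unweighted"),
    data.frame(covariate = bal$covariate, smd = bal$smd_weighted,
               weighted = "Weighted"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$smd, y = .data$covariate,
                                     colour = .data$weighted)) +
    ggplot2::geom_vline(xintercept = c(-0.1, 0.1), linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "solid",
                        colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Standardized mean difference", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
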