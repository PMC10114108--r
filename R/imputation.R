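# Multiple imputation by chained equations and Rubin pooling ------------------
#
# The engine is regression-draw MICE: continuous variables are imputed by a
# linear fit plus residual-scale noise, binary variables by a Bernoulli draw
# from fitted logistic probabilities, ordinal variables by sequential
# logistic draws. Income is imputed on the log scale; poverty and caseness
# are re-derived (dichotomized) from the imputed income and GHQ score after
# imputation, never imputed directly.

#' Imputation specification
#'
#' @param m number of imputed datasets (default 20).
#' @param max_iterations chained-equation cycles per dataset (default 10).
#' @param variables the analysis variable list used both for the
#'   high-missingness row exclusion and as the imputation universe
#'   (default: the standard panel analysis variables).
#' @param variable_models named character map variable -> family
#'   ("linear", "logistic", "ordinal"); unspecified variables get a family
#'   by type (binary -> logistic, `education` -> ordinal, else linear).
#' @param log_transform variables imputed on the log scale (income).
#' @param interactions list of c(variable, modifier) pairs: whenever both
#'   appear as predictors of a target, their product enters the design
#'   (default: income with the three effect modifiers).
#' @param high_missingness_threshold rows missing strictly more than this
#'   many of `variables` are excluded (default 9).
#' @param seed integer seed.
#' @return An `imputation_spec` list.
#' @export
imputation_spec <- function(m = 20L, max_iterations = 10L,
                            variables = c("income", "housing_costs",
                                          "employment", "benefits", "tenure",
                                          "marital", "n_children",
                                          "education", "sf12_pcs", "sf12_mcs",
                                          "ghq_score"),
                            variable_models = character(),
                            log_transform = "income",
                            interactions = list(c("income", "gender"),
                                                c("income", "education"),
                                                c("income", "age")),
                            high_missingness_threshold = 9L,
                            seed = 1L) {
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  if (high_missingness_threshold < 1)
    stop("high_missingness_threshold must be >= 1", call. = FALSE)
  structure(list(m = as.integer(m), max_iterations = as.integer(max_iterations),
                 variables = variables, variable_models = variable_models,
                 log_transform = log_transform, interactions = interactions,
                 high_missingness_threshold = as.integer(high_missingness_threshold),
                 seed = as.integer(seed)),
            class = "imputation_spec")
}

#' Exclude person-waves with high missingness
#'
#' Removes rows missing strictly more than the threshold count of the
#' declared analysis variables, and logs them.
#'
#' @param panel panel with NA cells.
#' @param spec an [imputation_spec()].
#' @return List: `panel` (retained rows), `exclusions` (data.frame of
#'   person_id, wave, n_missing for dropped rows).
#' @export
exclude_high_missingness <- function(panel, spec = imputation_spec()) {
  vars <- intersect(spec$variables, names(panel))
  nmiss <- rowSums(is.na(panel[, vars, drop = FALSE]))
  drop <- nmiss > spec$high_missingness_threshold
  log <- data.frame(person_id = panel$person_id[drop],
                    wave = panel$wave[drop],
                    n_missing = nmiss[drop])
  out <- panel[!drop, ]
  rownames(out) <- NULL
  list(panel = out, exclusions = log)
}

.default_family <- function(panel, v) {
  x <- panel[[v]][!is.na(panel[[v]])]
  if (v == "education") return("ordinal")
  if (all(x %in% c(0, 1))) return("logistic")
  "linear"
}

.impute_design <- function(data, target, predictors, spec) {
  terms <- character()
  for (p in predictors) {
    if (p %in% c("region", "wave")) terms <- c(terms, paste0("factor(", p, ")"))
    else terms <- c(terms, p)
  }
  for (pair in spec$interactions) {
    if (!target %in% pair && all(pair %in% predictors))
      terms <- c(terms, paste(pair, collapse = ":"))
  }
  stats::model.matrix(
    stats::as.formula(paste("~", paste(terms, collapse = " + "))), data)
}

.draw_linear <- function(X_obs, y_obs, X_mis) {
  qr_ <- qr(X_obs)
  keep <- qr_$pivot[seq_len(qr_$rank)]
  beta <- qr.coef(qr(X_obs[, keep, drop = FALSE]), y_obs)
  res <- y_obs - X_obs[, keep, drop = FALSE] %*% beta
  sigma <- sqrt(sum(res^2) / max(length(y_obs) - length(beta), 1))
  drop(X_mis[, keep, drop = FALSE] %*% beta) +
    stats::rnorm(nrow(X_mis), 0, sigma)
}

.draw_logistic <- function(X_obs, y_obs, X_mis) {
  fit <- suppressWarnings(stats::glm.fit(X_obs, y_obs,
                                         family = stats::binomial()))
  beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  p <- expit(drop(X_mis %*% beta))
  stats::rbinom(nrow(X_mis), 1, p)
}

.draw_ordinal <- function(X_obs, y_obs, X_mis) {
  # sequential logistic over ordered levels
  lev <- sort(unique(y_obs))
  n_mis <- nrow(X_mis)
  out <- rep(lev[1], n_mis)
  alive <- rep(TRUE, n_mis)          # still eligible for a higher level
  obs_alive <- rep(TRUE, length(y_obs))
  for (k in seq_along(lev)[-1]) {
    oa <- which(obs_alive)
    yk <- as.integer(y_obs[oa] >= lev[k])
    if (length(unique(yk)) < 2) break
    fit <- suppressWarnings(stats::glm.fit(X_obs[oa, , drop = FALSE], yk,
                                           family = stats::binomial()))
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    p <- expit(drop(X_mis[, , drop = FALSE] %*% beta))
    go <- alive & (stats::runif(n_mis) < p)
    out[go] <- lev[k]
    alive <- go
    obs_alive <- obs_alive & (y_obs >= lev[k])
  }
  out
}

#' Chained-equations multiple imputation
#'
#' Cycles variables in ascending order of missingness fraction for a fixed
#' number of iterations, drawing stochastic imputations (see module note).
#' Observed cells are never altered. After each dataset completes, income-
#' derived poverty and GHQ-derived caseness are re-dichotomized.
#'
#' @param panel panel after [exclude_high_missingness()].
#' @param spec an [imputation_spec()].
#' @return An `imputation_stack`: `datasets` (list of m complete panels),
#'   `trace` (data.frame: dataset, iteration, variable, mean of imputed
#'   values), `flags` (fit failures), `spec`.
#' @export
mice_impute <- function(panel, spec = imputation_spec()) {
  vars <- intersect(spec$variables, names(panel))
  miss_frac <- vapply(vars, function(v) mean(is.na(panel[[v]])), 0)
  to_impute <- names(sort(miss_frac[miss_frac > 0]))
  fams <- vapply(to_impute, function(v) {
    if (v %in% names(spec$variable_models)) spec$variable_models[[v]]
    else .default_family(panel, v)
  }, "")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)

  base_predictors <- function(v) {
    intersect(setdiff(unique(c("gender", "age", "wave", vars)), v),
              names(panel))
  }
  mask <- lapply(to_impute, function(v) which(is.na(panel[[v]])))
  names(mask) <- to_impute

  datasets <- vector("list", spec$m)
  trace <- list()
  flags <- character()
  for (d in seq_len(spec$m)) {
    set.seed(spec$seed + 1000L * d)
    cur <- panel
    # initial fill: random draws from the observed distribution
    for (v in to_impute) {
      obs <- cur[[v]][!is.na(cur[[v]])]
      cur[[v]][mask[[v]]] <- sample(obs, length(mask[[v]]), replace = TRUE)
    }
    n_iter <- if (length(to_impute)) spec$max_iterations else 0L
    for (it in seq_len(n_iter)) {
      for (v in to_impute) {
        midx <- mask[[v]]
        work <- cur
        logged <- v %in% spec$log_transform
        yv <- if (logged) log(pmax(work[[v]], 1e-8)) else work[[v]]
        X <- tryCatch(.impute_design(work, v, base_predictors(v), spec),
                      error = function(e) NULL)
        if (is.null(X)) { flags <- c(flags, paste(v, "design failed")); next }
        oidx <- setdiff(seq_len(nrow(work)), midx)
        drawn <- tryCatch(switch(fams[[v]],
          linear = .draw_linear(X[oidx, , drop = FALSE], yv[oidx],
                                X[midx, , drop = FALSE]),
          logistic = .draw_logistic(X[oidx, , drop = FALSE], yv[oidx],
                                    X[midx, , drop = FALSE]),
          ordinal = .draw_ordinal(X[oidx, , drop = FALSE], yv[oidx],
                                  X[midx, , drop = FALSE])),
          error = function(e) NULL)
        if (is.null(drawn)) {
          flags <- c(flags, paste0(v, " iteration ", it,
                                   ": fit failed, kept previous draws"))
          next
        }
        if (logged) drawn <- exp(drawn)
        if (v %in% c("ghq_score"))
          drawn <- pmin(pmax(round(drawn), 0L), 12L)
        if (v %in% c("n_children"))
          drawn <- pmin(pmax(round(drawn), 0L), 10L)
        cur[[v]][midx] <- drawn
        trace[[length(trace) + 1L]] <- data.frame(
          dataset = d, iteration = it, variable = v,
          mean_imputed = mean(as.numeric(drawn)))
      }
    }
    # dichotomize after imputation: poverty from imputed income, caseness
    # from imputed GHQ score
    if (all(c("income", "housing_costs") %in% names(cur)))
      cur <- derive_poverty(cur)
    if ("ghq_score" %in% names(cur))
      cur$ghq_case <- derive_caseness(cur$ghq_score)
    datasets[[d]] <- cur
  }
  structure(list(datasets = datasets,
                 trace = if (length(trace)) do.call(rbind, trace)
                         else data.frame(dataset = integer(), iteration = integer(),
                                         variable = character(),
                                         mean_imputed = numeric()),
                 flags = flags, spec = spec),
            class = "imputation_stack")
}

#' Serialize an imputation stack
#'
#' Writes the m completed panels as CSV files (`imputed_01.csv`, ...), the
#' convergence trace as `trace.csv`, and a JSON manifest holding the seed,
#' a stable hash of the specification, and the exclusion log if supplied.
#'
#' @param stack an `imputation_stack` from [mice_impute()].
#' @param dir output directory (created if needed).
#' @param exclusions optional exclusion log from
#'   [exclude_high_missingness()].
#' @return The directory path, invisibly.
#' @export
write_imputation_stack <- function(stack, dir, exclusions = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in seq_along(stack$datasets)) {
    utils::write.csv(stack$datasets[[d]],
                     file.path(dir, sprintf("imputed_%02d.csv", d)),
                     row.names = FALSE, na = "")
  }
  utils::write.csv(stack$trace, file.path(dir, "trace.csv"),
                   row.names = FALSE)
  spec_json <- jsonlite::toJSON(stack$spec[setdiff(names(stack$spec),
                                                   "seed")],
                                auto_unbox = TRUE, force = TRUE)
  spec_hash <- sum(as.integer(charToRaw(as.character(spec_json))) *
                   (seq_along(charToRaw(as.character(spec_json))) %% 31 + 1))
  jsonlite::write_json(
    list(m = stack$spec$m, seed = stack$spec$seed,
         spec_hash = spec_hash, flags = stack$flags,
         n_excluded = if (is.null(exclusions)) 0L else nrow(exclusions)),
    file.path(dir, "imputation_manifest.json"), auto_unbox = TRUE)
  if (!is.null(exclusions))
    utils::write.csv(exclusions, file.path(dir, "exclusions.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Rubin's-rules pooling of per-dataset estimates
#'
#' point = mean of estimates; between-variance = sample variance of the
#' estimates; total variance = mean within-variance + (1 + 1/m) between.
#'
#' @param estimates per-dataset point estimates (length m >= 2).
#' @param variances per-dataset squared standard errors (same length).
#' @return List of class `pooled_estimate`: `point`, `within_var`,
#'   `between_var`, `total_var`, `se`, `ci` (normal 95%), `m`.
#' @export
pool_rubin <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2 || length(variances) != m)
    stop("need >= 2 estimates with matching variances", call. = FALSE)
  point <- mean(estimates)
  within <- mean(variances)
  between <- stats::var(estimates)
  total <- within + (1 + 1 / m) * between
  se <- sqrt(total)
  structure(list(point = point, within_var = within, between_var = between,
                 total_var = total, se = se,
                 ci = point + c(-1.96, 1.96) * se, m = m),
            class = "pooled_estimate")
}
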