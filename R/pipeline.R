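# Pipeline orchestration ------------------------------------------------------

#' Run configuration
#'
#' @param scenario preset name (see [scenario_config()]) or NULL when
#'   `data_path` supplies a panel CSV.
#' @param n_individuals,n_waves simulated panel size.
#' @param data_path optional path of an existing long panel CSV.
#' @param stages stages to run, in pipeline order; later stages require
#'   earlier ones (or files from a previous run in `out_dir`).
#' @param impute TRUE for multiple imputation, FALSE for complete-case.
#' @param m imputed datasets when `impute`.
#' @param bootstrap_n bootstrap replicates for CIs (0 disables).
#' @param seed global seed; stage seeds derive from it via [stage_seed()].
#' @param out_dir output directory.
#' @param sim_overrides named list of [sim_config()] overrides.
#' @return A `run_config` list.
#' @export
run_config <- function(scenario = "default", n_individuals = 2000L,
                       n_waves = 6L, data_path = NULL,
                       stages = c("simulate", "derive", "impute", "weight",
                                  "estimate", "transitions", "strata",
                                  "fe_compare", "report"),
                       impute = TRUE, m = 5L, bootstrap_n = 0L,
                       seed = 1L, out_dir = tempfile("povmsm_run_"),
                       sim_overrides = list()) {
  structure(list(scenario = scenario, n_individuals = as.integer(n_individuals),
                 n_waves = as.integer(n_waves), data_path = data_path,
                 stages = stages, impute = impute, m = as.integer(m),
                 bootstrap_n = as.integer(bootstrap_n),
                 seed = as.integer(seed), out_dir = out_dir,
                 sim_overrides = sim_overrides),
            class = "run_config")
}

.complete_case <- function(tab, terms) {
  vars <- unique(sub("^factor\\((.*)\\)$", "\\1", terms))
  vars <- intersect(c(vars, "a", "ghq_case"), names(tab))
  tab[stats::complete.cases(tab[, vars, drop = FALSE]), ]
}

#' Run the configured pipeline end to end
#'
#' Executes simulate -> derive -> impute -> weight -> estimate
#' (+ transitions, strata, fe-compare) as configured, writing a tidy
#' results CSV, balance CSV, love plot and JSON manifest to the output
#' directory. Every stochastic stage is seeded deterministically from the
#' global seed, so the same config gives byte-identical result files.
#'
#' @param config a [run_config()].
#' @return Invisibly, a results bundle: list with `panel`, `analysis`,
#'   `weights`, `balance`, `results` (tidy data.frame), `fe`, `warnings`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages
  bundle <- list(out_dir = cfg$out_dir, warnings = character())
  boot <- if (cfg$bootstrap_n > 0)
    list(n_replicates = cfg$bootstrap_n,
         seed = stage_seed(cfg$seed, "bootstrap")) else NULL

  if ("simulate" %in% stages) {
    if (!is.null(cfg$data_path)) {
      bundle$panel <- read_panel(cfg$data_path)
    } else {
      sc <- do.call(scenario_config,
                    c(list(name = cfg$scenario,
                           n_individuals = cfg$n_individuals,
                           seed = stage_seed(cfg$seed, "simulate"),
                           n_waves = cfg$n_waves), cfg$sim_overrides))
      panel <- generate_panel(sc)
      if (sc$missingness$rate > 0 || sc$attrition_rate > 0)
        panel <- impose_missingness(panel, sc)$panel
      bundle$panel <- panel
      bundle$sim_config <- sc
    }
    write_panel(bundle$panel, file.path(cfg$out_dir, "panel.csv"))
  }
  .write_manifest(cfg, bundle)
  if (!any(c("derive", "impute", "weight", "estimate", "transitions",
             "strata", "fe_compare", "report") %in% stages))
    return(invisible(bundle))

  if ("derive" %in% stages) {
    panel <- derive_poverty(bundle$panel)
    if (!"ghq_case" %in% names(panel) ||
        anyNA(panel$ghq_case) != anyNA(panel$ghq_score))
      panel$ghq_case <- derive_caseness(panel$ghq_score)
    bundle$derived <- panel
  }

  tables <- NULL
  if ("impute" %in% stages && cfg$impute) {
    ispec <- imputation_spec(m = cfg$m, seed = stage_seed(cfg$seed, "impute"))
    ex <- exclude_high_missingness(bundle$derived, ispec)
    stack <- mice_impute(ex$panel, ispec)
    bundle$imputation <- stack
    bundle$exclusions <- ex$exclusions
    write_imputation_stack(stack, file.path(cfg$out_dir, "imputation"),
                           ex$exclusions)
    tables <- lapply(stack$datasets, build_analysis_table)
  } else {
    tab <- build_analysis_table(bundle$derived)
    tables <- list(.complete_case(tab, default_adjustment_set()))
  }
  bundle$analysis <- tables[[1L]]
  utils::write.csv(tables[[1L]], file.path(cfg$out_dir, "analysis.csv"),
                   row.names = FALSE, na = "")
  .write_codebook(file.path(cfg$out_dir, "codebook.csv"))

  esp <- exposure_spec()
  osp <- outcome_spec()
  if ("weight" %in% stages) {
    ws <- compute_stabilized_weights(tables[[1L]], esp)
    bundle$weights <- ws
    bundle$balance <- balance_table(tables[[1L]], ws, esp)
    utils::write.csv(bundle$balance, file.path(cfg$out_dir, "balance.csv"),
                     row.names = FALSE)
    grDevices::pdf(file.path(cfg$out_dir, "love_plot.pdf"), width = 7,
                   height = 6)
    print(plot_balance(bundle$balance))
    grDevices::dev.off()
    jsonlite::write_json(as.list(ws$summary),
                         file.path(cfg$out_dir, "weights_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    if (abs(ws$summary[["mean"]] - 1) > 0.1)
      bundle$warnings <- c(bundle$warnings,
                           sprintf("stabilized weight mean %.3f outside [0.9, 1.1]",
                                   ws$summary[["mean"]]))
  }

  results <- list()
  pool_over <- function(fit_one) {
    # fit on each imputed dataset, pool rd/paf/or by Rubin's rules when m > 1
    ests <- lapply(tables, fit_one)
    if (length(ests) == 1L) return(ests[[1L]])
    pooled <- ests[[1L]]
    for (q in c("rd", "or_", "prev_unexposed", "prev_total", "paf")) {
      vals <- vapply(ests, function(e) e[[q]], 0)
      if (!is.null(ests[[1L]]$se)) {
        pr <- pool_rubin(vals, vapply(ests, function(e) e$se[[q]]^2, 0))
        pooled[[q]] <- pr$point
        pooled$se[[q]] <- pr$se
        pooled$ci[[q]] <- pr$ci
      } else {
        pooled[[q]] <- mean(vals)
      }
    }
    pooled$paf <- compute_paf(pooled$prev_total, pooled$prev_unexposed)
    pooled
  }

  if ("estimate" %in% stages) {
    est <- pool_over(function(tb) {
      if (is.null(boot))
        estimate_effect(tb, compute_stabilized_weights(tb, esp), osp)
      else bootstrap_estimate(tb, esp, osp, n_replicates = boot$n_replicates,
                              seed = boot$seed)
    })
    results[["binary.all"]] <- tidy_estimates(est, "binary", "all")
  }
  if ("transitions" %in% stages) {
    for (em in c("into", "outof")) {
      est <- tryCatch(pool_over(function(tb)
        estimate_transitions(tb, em, esp, osp, bootstrap = boot)),
        error = function(e) e)
      results[[paste0(em, ".all")]] <- tidy_estimates(est, em, "all")
    }
  }
  if ("strata" %in% stages) {
    for (s in c("gender", "education", "age_group")) {
      ests <- estimate_stratified(tables[[1L]], s, esp, osp, bootstrap = boot)
      results[[paste0("binary.", s)]] <-
        tidy_estimates(ests, rep("binary", length(ests)),
                       paste0(s, "=", names(ests)))
      for (em in c("into", "outof")) {
        tabs <- if (s == "age_group") {
          tt <- tables[[1L]]
          tt$age_group <- ifelse(tt$age <= 40, "younger", "older")
          split(tt, tt$age_group)
        } else split(tables[[1L]], tables[[1L]][[s]])
        drop_term <- switch(s, gender = "gender",
                            education = "factor(education)", age_group = NULL)
        esp_s <- exposure_spec(setdiff(esp$denominator, drop_term),
                               setdiff(esp$numerator, drop_term))
        osp_s <- outcome_spec(setdiff(osp$covariates, drop_term))
        ests_t <- lapply(tabs, function(tb) tryCatch(
          estimate_transitions(tb, em, esp_s, osp_s, bootstrap = boot),
          error = function(e) e))
        results[[paste0(em, ".", s)]] <-
          tidy_estimates(ests_t, rep(em, length(ests_t)),
                         paste0(s, "=", names(ests_t)))
      }
    }
  }
  if (length(results)) {
    bundle$results <- do.call(rbind, results)
    rownames(bundle$results) <- NULL
    utils::write.csv(bundle$results, file.path(cfg$out_dir, "results.csv"),
                     row.names = FALSE, na = "")
  }

  if ("fe_compare" %in% stages) {
    fe_covs <- c("employment", "employment_lag", "benefits_lag",
                 "tenure_lag", "marital_lag", "n_children_lag",
                 "sf12_pcs_lag", "sf12_mcs_lag", "y_lag", "a_lag",
                 "age", "age2", "wave_f")
    bundle$fe <- list(
      unadjusted = tryCatch(
        fit_conditional_logit(tables[[1L]], c("wave_f")),
        error = function(e) e),
      adjusted = tryCatch(
        fit_conditional_logit(tables[[1L]], fe_covs),
        error = function(e) e))
    fe_rows <- do.call(rbind, lapply(names(bundle$fe), function(nm) {
      f <- bundle$fe[[nm]]
      if (inherits(f, "error"))
        data.frame(method = paste0("fe_conditional_", nm), or_ = NA_real_,
                   prob_contrast = NA_real_, n_informative = NA_integer_)
      else data.frame(method = paste0("fe_conditional_", nm), or_ = f$or_,
                      prob_contrast = f$prob_contrast,
                      n_informative = f$n_informative)
    }))
    utils::write.csv(fe_rows, file.path(cfg$out_dir, "fe_comparison.csv"),
                     row.names = FALSE, na = "")
  }
  .write_manifest(cfg, bundle)
  invisible(bundle)
}

.write_manifest <- function(cfg, bundle) {
  manifest <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    seed = cfg$seed,
    stage_seeds = stats::setNames(
      lapply(cfg$stages, function(s) stage_seed(cfg$seed, s)), cfg$stages),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("povertymsm")),
    warnings = bundle$warnings)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       null = "null")
  invisible(NULL)
}

.write_codebook <- function(path) {
  cb <- data.frame(
    variable = c("person_id", "household_id", "wave", "income",
                 "housing_costs", "n_adults", "n_children", "gender",
                 "ethnicity", "education", "employment", "benefits",
                 "tenure", "marital", "region", "age", "sf12_pcs",
                 "sf12_mcs", "ghq_score", "ghq_case", "a", "eq_income"),
    coding = c("integer id", "integer id", "integer wave number",
               "household income, currency/month",
               "housing costs, currency/month", "adults in household",
               "children under 14", "0 male / 1 female",
               "0 White / 1 non-White", "1 low / 2 medium / 3 high",
               "0 not employed / 1 employed", "0/1 receives benefits",
               "0 renter / 1 owner", "0 single / 1 coupled",
               "generic categorical 1-4", "years", "SF-12 physical score",
               "SF-12 mental score", "GHQ-12 score 0-12",
               "1 if ghq_score >= 4 (CMD caseness)",
               "1 if eq_income < 60% of wave median (poverty)",
               "equivalized after-housing-cost income"))
  utils::write.csv(cb, path, row.names = FALSE)
  invisible(NULL)
}

#' Human-readable summary of a results bundle
#'
#' @param bundle the list returned by [run_pipeline()] (needs `results`).
#' @param digits significant digits for display.
#' @return The formatted character vector, invisibly; printed to console.
#' @export
report_results <- function(bundle, digits = 3) {
  if (is.null(bundle$results)) stop("bundle has no results", call. = FALSE)
  res <- bundle$results
  need <- c("estimand", "stratum", "rd", "or_", "prev_unexposed", "paf")
  if (!all(need %in% names(res)))
    stop("results missing columns: ",
         paste(setdiff(need, names(res)), collapse = ", "), call. = FALSE)
  fmt <- function(x, lo, hi) {
    ifelse(is.na(x), "-",
           ifelse(is.na(lo), sprintf("%.*g", digits, x),
                  sprintf("%.*g (%.*g, %.*g)", digits, x, digits, lo,
                          digits, hi)))
  }
  lines <- c("Causal effect estimates of poverty on CMD",
             "=========================================")
  for (i in seq_len(nrow(res))) {
    lines <- c(lines, sprintf(
      "%-8s %-18s RD %s pp | OR %s | prev(unexp) %s%% | PAF %s%%",
      res$estimand[i], res$stratum[i],
      fmt(res$rd[i], res$rd_lo[i], res$rd_hi[i]),
      fmt(res$or_[i], res$or_lo[i], res$or_hi[i]),
      fmt(res$prev_unexposed[i], NA, NA),
      fmt(res$paf[i], res$paf_lo[i], res$paf_hi[i])))
  }
  if (!is.null(bundle$balance)) {
    worst <- max(abs(bundle$balance$smd_weighted))
    lines <- c(lines, sprintf("Balance: max weighted |SMD| = %.3f%s", worst,
                              if (worst >= 0.1) "  ** above 0.1 **" else ""))
  }
  if (length(bundle$warnings))
    lines <- c(lines, "Warnings:", paste(" -", bundle$warnings))
  cat(lines, sep = "\n")
  invisible(lines)
}
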