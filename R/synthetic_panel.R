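# Synthetic household panel generator -----------------------------------------
#
# Emulates the causal structure assumed by the analysis: time-invariant
# confounders (gender, ethnicity, education), time-varying confounders drawn
# given the previous wave's state (employment, benefits, tenure, marital
# status, children, physical/mental health, age), a log-income process with
# AR(1) persistence and health selection (lagged CMD lowers income), a
# relative poverty line recomputed each wave, and a latent-logit CMD outcome.
# Exposure-outcome feedback runs through income: prior CMD reduces income and
# hence raises subsequent poverty risk.

#' Simulation configuration for the synthetic panel
#'
#' Defaults are calibrated once so the generated panel resembles a UK
#' household panel of working-age adults: roughly 22% poverty prevalence
#' (equivalized after-housing-cost income below 60% of the wave median) and
#' roughly 20% CMD prevalence (GHQ-12 caseness).
#'
#' @param n_individuals number of persons.
#' @param n_waves number of annual waves (>= 2; lags need a prior wave).
#' @param seed integer seed; identical config + seed gives identical panels.
#' @param exposure_effect log-odds of current poverty on CMD caseness.
#' @param onset_effect additional log-odds applying only to transitions into
#'   poverty (A_t = 1, A_{t-1} = 0); 0 gives a symmetric short-term effect.
#' @param exposure_effect_gender additional exposure log-odds for women
#'   (gender = 1); nonzero values create genuine effect modification.
#' @param a_lag_effect log-odds of lagged poverty on CMD.
#' @param y_lag_effect log-odds of lagged CMD on current CMD (state
#'   dependence).
#' @param selection_effect effect of lagged CMD on log household income
#'   (health selection; negative means prior CMD lowers income).
#' @param confounder_effects named list of log-odds on the CMD latent model.
#'   Covariate codings: `employment`/`employment_lag` (0/1 at t and t-1),
#'   `benefits`, `tenure` (1 = owner), `marital` (1 = coupled), `children`
#'   (count), all lagged; `education` applied to (3 - level) so low education
#'   raises risk; `physical` and `mcs` applied to (50 - lagged score)/10;
#'   `age` and `age2` applied to (age - 45)/10 and its square.
#' @param baseline_cmd_logit intercept of the CMD latent model.
#' @param person_sd SD of a person-level normal intercept on the CMD logit
#'   (0 = none; positive values create unobserved heterogeneity for
#'   fixed-effects comparisons).
#' @param income_params list: `mu` (log mean monthly income), `sd` (SD of the
#'   logistic income innovation), `rho` (AR(1) persistence), `housing_frac`
#'   and `housing_sd` (housing costs as a noisy fraction of income),
#'   `emp_gain`, `educ_gain`, `pcs_gain` (covariate loadings on log income),
#'   `partner_mult` (household income multiplier when coupled).
#' @param missingness list: `rate` (overall cell missingness in [0,1]),
#'   `mar` (named logit-scale coefficients of missingness on observed
#'   `employment`, `gender` and scaled `age`), and optional `columns`
#'   restricting which columns receive missing cells.
#' @param attrition_rate per-wave monotone dropout probability in [0,1].
#' @param randomize_exposure NULL (poverty derived from income, the default)
#'   or a probability: exposure assigned at random with that probability,
#'   severing the income -> exposure link (used for design checks).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals,
                       n_waves = 9L,
                       seed = 1L,
                       exposure_effect = 0.15,
                       onset_effect = 0,
                       exposure_effect_gender = 0,
                       a_lag_effect = 0,
                       y_lag_effect = 1.1,
                       selection_effect = -0.35,
                       confounder_effects = list(
                         employment = -0.45, employment_lag = -0.15,
                         benefits = 0.35, tenure = -0.25, marital = -0.20,
                         children = 0.08, education = 0.18,
                         physical = 0.30, mcs = 0.40,
                         age = 0.05, age2 = -0.04),
                       baseline_cmd_logit = -1.45,
                       person_sd = 0,
                       income_params = list(
                         mu = log(2300), sd = 0.45, rho = 0.4,
                         housing_frac = 0.28, housing_sd = 0.03,
                         emp_gain = 0.85, educ_gain = 0.28, pcs_gain = 0.05,
                         partner_mult = 1.6),
                       missingness = list(
                         rate = 0.08,
                         mar = c(employment = -0.5, age = 0.15)),
                       attrition_rate = 0.04,
                       randomize_exposure = NULL) {
  cfg <- list(
    n_individuals = as.integer(n_individuals), n_waves = as.integer(n_waves),
    seed = as.integer(seed), exposure_effect = exposure_effect,
    onset_effect = onset_effect,
    exposure_effect_gender = exposure_effect_gender,
    a_lag_effect = a_lag_effect,
    y_lag_effect = y_lag_effect, selection_effect = selection_effect,
    confounder_effects = confounder_effects,
    baseline_cmd_logit = baseline_cmd_logit, person_sd = person_sd,
    income_params = income_params, missingness = missingness,
    attrition_rate = attrition_rate, randomize_exposure = randomize_exposure)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  if (!is.finite(cfg$n_individuals) || cfg$n_individuals <= 0)
    stop("invalid config: n_individuals must be positive", call. = FALSE)
  if (cfg$n_waves < 2)
    stop("invalid config: n_waves must be >= 2 (lags need a prior wave)",
         call. = FALSE)
  r <- cfg$missingness$rate
  if (!is.numeric(r) || r < 0 || r > 1)
    stop("invalid config: missingness rate must be in [0, 1]", call. = FALSE)
  if (cfg$attrition_rate < 0 || cfg$attrition_rate > 1)
    stop("invalid config: attrition_rate must be in [0, 1]", call. = FALSE)
  if (!is.null(cfg$randomize_exposure) &&
      (cfg$randomize_exposure < 0 || cfg$randomize_exposure > 1))
    stop("invalid config: randomize_exposure must be in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' Named scenario presets
#'
#' @param name one of "default", "null_effect", "strong_selection",
#'   "no_confounding".
#' @param n_individuals,seed passed to [sim_config()].
#' @param ... further overrides of [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
scenario_config <- function(name = c("default", "null_effect",
                                     "strong_selection", "no_confounding"),
                            n_individuals, seed = 1L, ...) {
  name <- match.arg(name)
  extra <- switch(name,
    default = list(),
    null_effect = list(exposure_effect = 0, onset_effect = 0),
    strong_selection = list(selection_effect = -1.2, y_lag_effect = 1.4),
    no_confounding = list(
      selection_effect = 0,
      confounder_effects = list(
        employment = 0, employment_lag = 0, benefits = 0, tenure = 0,
        marital = 0, children = 0, education = 0, physical = 0, mcs = 0,
        age = 0, age2 = 0),
      y_lag_effect = 0,
      income_params = list(mu = log(2300), sd = 0.45, rho = 0.4,
                           housing_frac = 0.28, housing_sd = 0.03,
                           emp_gain = 0, educ_gain = 0, pcs_gain = 0,
                           partner_mult = 1.6)))
  args <- utils::modifyList(
    c(list(n_individuals = n_individuals, seed = seed), extra), list(...))
  do.call(sim_config, args)
}

#' Read a simulation configuration from a key-value file
#'
#' The file is plain YAML whose top-level keys are [sim_config()] argument
#' names; an optional `scenario` key selects a [scenario_config()] preset
#' that the remaining keys then override.
#'
#' @param path file path.
#' @return A `sim_config`.
#' @export
sim_config_from_file <- function(path) {
  kv <- yaml::read_yaml(path)
  if (!is.null(kv$scenario)) {
    name <- kv$scenario
    kv$scenario <- NULL
    do.call(scenario_config, c(list(name = name), kv))
  } else {
    do.call(sim_config, kv)
  }
}

# latent CMD linear predictor at wave t, exposure terms excluded
cmd_eta0 <- function(cfg, st) {
  ce <- cfg$confounder_effects
  cfg$baseline_cmd_logit +
    cfg$y_lag_effect * st$y_lag +
    cfg$a_lag_effect * st$a_lag +
    ce$employment * st$employment + ce$employment_lag * st$employment_lag +
    ce$benefits * st$benefits_lag + ce$tenure * st$tenure_lag +
    ce$marital * st$marital_lag + ce$children * st$children_lag +
    ce$education * (3 - st$education) +
    ce$physical * (50 - st$pcs_lag) / 10 + ce$mcs * (50 - st$mcs_lag) / 10 +
    ce$age * (st$age - 45) / 10 + ce$age2 * ((st$age - 45) / 10)^2 +
    st$u
}

# exposure-term contribution for a given (A, A_lag) and gender
cmd_beta <- function(cfg, a, a_lag, gender = 0) {
  (cfg$exposure_effect + (cfg$exposure_effect_gender %||% 0) * gender) * a +
    cfg$onset_effect * a * (1 - a_lag)
}

# advance the time-varying state from wave t-1 to wave t (draws new
# employment, benefits, tenure, marital, children, pcs, income, exposure)
advance_wave <- function(cfg, st, t) {
  n <- length(st$employment)
  ip <- cfg$income_params
  if (t == 1L) {
    employment <- stats::rbinom(n, 1, expit(1.2 + 0.4 * (st$education - 2)))
  } else {
    employment <- stats::rbinom(n, 1, expit(-1.1 + 3.0 * st$employment +
                                            0.3 * (st$education - 2) -
                                            0.3 * st$y_lag))
  }
  benefits <- stats::rbinom(n, 1, expit(-1.8 + 1.4 * (1 - employment) +
                                        if (t == 1L) 0 else 1.2 * st$benefits))
  tenure <- if (t == 1L)
    stats::rbinom(n, 1, expit(0.4 + 0.5 * (st$education - 2)))
  else
    stats::rbinom(n, 1, expit(-2.5 + 5 * st$tenure + 0.3 * (st$education - 2)))
  marital <- if (t == 1L) stats::rbinom(n, 1, 0.65)
             else stats::rbinom(n, 1, expit(-2.8 + 5.6 * st$marital))
  children <- if (t == 1L) pmin(stats::rpois(n, 0.9), 4L)
              else pmax(pmin(st$children +
                               stats::rbinom(n, 1, 0.05 * (st$children < 4)) -
                               stats::rbinom(n, 1, 0.06 * (st$children > 0)),
                             4L), 0L)
  age <- st$age0 + (t - 1L)
  pcs_mu <- 50 - 0.08 * (age - 45)
  pcs <- if (t == 1L) pcs_mu + stats::rnorm(n, 0, 8)
         else pcs_mu + 0.8 * (st$pcs - (pcs_mu + 0.08)) + stats::rnorm(n, 0, 4.8)

  base <- ip$mu + ip$educ_gain * (st$education - 2) +
    ip$emp_gain * (employment - 1) + ip$pcs_gain * (pcs - 50) / 10 +
    cfg$selection_effect * st$y_lag
  eps <- stats::rlogis(n, 0, ip$sd * sqrt(3) / pi)
  log_inc <- if (t == 1L) base + eps
             else base + ip$rho * (st$log_inc - st$base) + eps
  pers_inc <- exp(log_inc)
  hh_inc <- pers_inc * ifelse(marital == 1, ip$partner_mult, 1)
  hfrac <- pmin(pmax(ip$housing_frac + stats::rnorm(n, 0, ip$housing_sd),
                     0.05), 0.6)
  housing <- hh_inc * hfrac
  scale <- 1 + 0.5 * marital + 0.3 * children
  eq_inc <- (hh_inc - housing) / scale

  if (is.null(cfg$randomize_exposure)) {
    line <- 0.6 * stats::median(eq_inc)
    a <- as.integer(eq_inc < line)
  } else {
    a <- stats::rbinom(n, 1, cfg$randomize_exposure)
  }

  list(employment = employment, benefits = benefits, tenure = tenure,
       marital = marital, children = children, age = age, pcs = pcs,
       log_inc = log_inc, base = base, hh_inc = hh_inc, housing = housing,
       scale = scale, a = a)
}

#' Generate a complete synthetic person-wave panel
#'
#' One row per person-wave, no missing values ([impose_missingness()] is a
#' separate step). Household income, housing costs and household composition
#' are emitted so the poverty exposure is re-derivable downstream; the `a`
#' and `ghq_case` columns carry the generative truth.
#'
#' @param config a [sim_config()].
#' @return A data.frame panel sorted by person then wave.
#' @export
generate_panel <- function(config) {
  validate_sim_config(config)
  cfg <- config
  n <- cfg$n_individuals
  withr_seed <- cfg$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(withr_seed)

  gender <- stats::rbinom(n, 1, 0.5)
  ethnicity <- stats::rbinom(n, 1, 0.14)
  education <- sample(1:3, n, replace = TRUE, prob = c(0.20, 0.45, 0.35))
  region <- sample(1:4, n, replace = TRUE)
  age0 <- sample(25:60, n, replace = TRUE)
  u <- if (cfg$person_sd > 0) stats::rnorm(n, 0, cfg$person_sd) else numeric(n)

  st <- list(education = education, age0 = age0, u = u,
             y_lag = integer(n), a_lag = integer(n),
             employment = integer(n), benefits = integer(n),
             tenure = integer(n), marital = integer(n), children = integer(n),
             pcs = numeric(n), mcs_lag = rep(50, n), pcs_lag = rep(50, n),
             log_inc = numeric(n), base = numeric(n))

  rows <- vector("list", cfg$n_waves)
  for (t in seq_len(cfg$n_waves)) {
    w <- advance_wave(cfg, st, t)
    st_t <- list(y_lag = st$y_lag, a_lag = st$a_lag,
                 employment = w$employment,
                 employment_lag = if (t == 1L) w$employment else st$employment,
                 benefits_lag = if (t == 1L) w$benefits else st$benefits,
                 tenure_lag = if (t == 1L) w$tenure else st$tenure,
                 marital_lag = if (t == 1L) w$marital else st$marital,
                 children_lag = if (t == 1L) w$children else st$children,
                 education = education, age = w$age,
                 pcs_lag = if (t == 1L) w$pcs else st$pcs,
                 mcs_lag = st$mcs_lag, u = u)
    eta0 <- cmd_eta0(cfg, st_t)
    eta <- eta0 + cmd_beta(cfg, w$a, st$a_lag, gender)
    y <- stats::rbinom(n, 1, expit(eta))
    mcs <- 50 - 6 * y + stats::rnorm(n, 0, 6)
    # GHQ-12 score consistent with caseness (score >= 4 iff case)
    p <- expit(eta)
    ghq <- ifelse(y == 1,
                  4L + stats::rbinom(n, 8, 0.1 + 0.6 * p),
                  stats::rbinom(n, 3, 0.8 * p))

    rows[[t]] <- data.frame(
      person_id = seq_len(n), household_id = seq_len(n), wave = t,
      income = w$hh_inc, housing_costs = w$housing,
      n_adults = 1L + w$marital, n_children = w$children,
      gender = gender, ethnicity = ethnicity, education = education,
      employment = w$employment, benefits = w$benefits, tenure = w$tenure,
      marital = w$marital, region = region, age = w$age,
      sf12_pcs = w$pcs, sf12_mcs = mcs,
      ghq_score = as.integer(ghq), ghq_case = y, a = w$a)

    st$y_lag <- y; st$a_lag <- w$a
    st$employment <- w$employment; st$benefits <- w$benefits
    st$tenure <- w$tenure; st$marital <- w$marital; st$children <- w$children
    st$pcs_lag <- st$pcs; st$pcs <- w$pcs; st$mcs_lag <- mcs
    st$log_inc <- w$log_inc; st$base <- w$base
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$person_id, out$wave), ]
  rownames(out) <- NULL
  out
}

#' Counterfactual oracle truth for a scenario
#'
#' Simulates the natural-course panel at large n and, at every analysis wave
#' (t >= 2), evaluates each person's CMD probability with exposure forced to
#' 1 and to 0 while all earlier history stays at its natural values. The
#' average difference is the true short-term causal risk difference; the
#' restricted averages over rows with lagged exposure 0 (resp. 1) give the
#' transition-into (resp. out-of) truths on the same reference populations
#' the estimators use.
#'
#' @param config a [sim_config()]; `n_individuals` is replaced by `n_mc`.
#' @param n_mc Monte-Carlo sample size (>= 10000).
#' @return List of class `oracle_truth`: `true_rd`, `true_or`,
#'   `true_rd_into`, `true_rd_outof` (percentage points), and Monte-Carlo
#'   standard errors `mc_se`, `mc_se_into`, `mc_se_outof`.
#' @export
compute_oracle_truth <- function(config, n_mc = 100000L) {
  if (n_mc < 10000L) stop("n_mc must be >= 10000", call. = FALSE)
  cfg <- config
  cfg$n_individuals <- as.integer(n_mc)
  validate_sim_config(cfg)
  n <- cfg$n_individuals
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(cfg$seed + 77L)

  gender <- stats::rbinom(n, 1, 0.5)
  education <- sample(1:3, n, replace = TRUE, prob = c(0.20, 0.45, 0.35))
  age0 <- sample(25:60, n, replace = TRUE)
  u <- if (cfg$person_sd > 0) stats::rnorm(n, 0, cfg$person_sd) else numeric(n)
  # (oracle population mirrors generate_panel draws)

  st <- list(education = education, age0 = age0, u = u,
             y_lag = integer(n), a_lag = integer(n),
             employment = integer(n), benefits = integer(n),
             tenure = integer(n), marital = integer(n), children = integer(n),
             pcs = numeric(n), mcs_lag = rep(50, n), pcs_lag = rep(50, n),
             log_inc = numeric(n), base = numeric(n))

  d_all <- list(); d_into <- list(); d_out <- list()
  p1_all <- list(); p0_all <- list(); pid_all <- list()
  for (t in seq_len(cfg$n_waves)) {
    w <- advance_wave(cfg, st, t)
    st_t <- list(y_lag = st$y_lag, a_lag = st$a_lag,
                 employment = w$employment,
                 employment_lag = if (t == 1L) w$employment else st$employment,
                 benefits_lag = if (t == 1L) w$benefits else st$benefits,
                 tenure_lag = if (t == 1L) w$tenure else st$tenure,
                 marital_lag = if (t == 1L) w$marital else st$marital,
                 children_lag = if (t == 1L) w$children else st$children,
                 education = education, age = w$age,
                 pcs_lag = if (t == 1L) w$pcs else st$pcs,
                 mcs_lag = st$mcs_lag, u = u)
    eta0 <- cmd_eta0(cfg, st_t)
    if (t >= 2L) {
      keep <- w$age >= 25 & w$age <= 64
      p1 <- expit(eta0 + cmd_beta(cfg, 1, st$a_lag, gender))
      p0 <- expit(eta0)
      d <- p1 - p0
      d_all[[t]] <- d[keep]
      p1_all[[t]] <- p1[keep]; p0_all[[t]] <- p0[keep]
      pid_all[[t]] <- which(keep)
      d_into[[t]] <- d[keep & st$a_lag == 0]
      d_out[[t]] <- d[keep & st$a_lag == 1]
    }
    eta <- eta0 + cmd_beta(cfg, w$a, st$a_lag, gender)
    y <- stats::rbinom(n, 1, expit(eta))
    mcs <- 50 - 6 * y + stats::rnorm(n, 0, 6)
    st$y_lag <- y; st$a_lag <- w$a
    st$employment <- w$employment; st$benefits <- w$benefits
    st$tenure <- w$tenure; st$marital <- w$marital; st$children <- w$children
    st$pcs_lag <- st$pcs; st$pcs <- w$pcs; st$mcs_lag <- mcs
    st$log_inc <- w$log_inc; st$base <- w$base
  }
  d <- unlist(d_all); di <- unlist(d_into); do_ <- unlist(d_out)
  p1 <- mean(unlist(p1_all)); p0 <- mean(unlist(p0_all))
  # cluster-aware MC standard error via person-level means
  pid <- unlist(pid_all)
  pm <- tapply(d, pid, mean)
  mc_se <- 100 * stats::sd(pm) / sqrt(length(pm))
  mcse_of <- function(x) if (length(x) > 1) 100 * stats::sd(x) / sqrt(length(x)) else NA_real_
  out <- list(
    true_rd = 100 * mean(d),
    true_or = (p1 / (1 - p1)) / (p0 / (1 - p0)),
    true_rd_into = 100 * mean(di),
    true_rd_outof = if (length(do_)) -100 * mean(do_) else NA_real_,
    mc_se = mc_se,
    mc_se_into = mcse_of(di),
    mc_se_outof = mcse_of(do_),
    n_rows = length(d))
  class(out) <- "oracle_truth"
  out
}

#' Impose missing-at-random cell missingness and monotone attrition
#'
#' Cell-level missingness probabilities depend only on always-observed
#' covariates (employment, age), per a logistic model whose intercept is
#' calibrated so the realized overall rate matches `config$missingness$rate`.
#' Attrition removes all of a person's rows from a random dropout wave
#' onward (monotone: once gone, gone). GHQ score and caseness go missing
#' together, as caseness is derived from the score.
#'
#' @param panel a complete panel from [generate_panel()].
#' @param config the [sim_config()] used (rate, MAR coefficients, attrition).
#' @return List: `panel` (with NA cells and attrited rows removed) and
#'   `miss_ind` (logical indicator table aligned to the returned panel).
#' @export
impose_missingness <- function(panel, config) {
  validate_sim_config(config)
  ms <- config$missingness
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed + 311L)

  # monotone attrition from wave 2 on
  if (config$attrition_rate > 0) {
    persons <- unique(panel$person_id)
    tmax <- max(panel$wave)
    # geometric dropout wave; > tmax means retained throughout
    drop_wave <- 1L + stats::rgeom(length(persons), config$attrition_rate) + 1L
    names(drop_wave) <- persons
    panel <- panel[panel$wave < drop_wave[as.character(panel$person_id)], ]
  }

  eligible <- intersect(
    ms$columns %||% c("income", "housing_costs", "employment", "benefits",
                      "tenure", "marital", "n_children", "education",
                      "sf12_pcs", "sf12_mcs", "ghq_score"), names(panel))
  miss_ind <- matrix(FALSE, nrow(panel), length(eligible),
                     dimnames = list(NULL, eligible))
  if (ms$rate > 0) {
    mar_of <- function(v) if (v %in% names(ms$mar)) ms$mar[[v]] else 0
    z <- mar_of("employment") * (panel$employment - mean(panel$employment)) +
         mar_of("gender") * (panel$gender - mean(panel$gender)) +
         mar_of("age") * (panel$age - mean(panel$age)) / 10
    # calibrate intercept so mean probability equals the target rate
    f <- function(c0) mean(expit(c0 + z)) - ms$rate
    c0 <- stats::uniroot(f, c(-20, 20))$root
    pmiss <- expit(c0 + z)
    for (v in eligible) {
      hit <- stats::runif(nrow(panel)) < pmiss
      miss_ind[, v] <- hit
      panel[[v]][hit] <- NA
    }
    if ("ghq_case" %in% names(panel) && "ghq_score" %in% colnames(miss_ind))
      panel$ghq_case[miss_ind[, "ghq_score"]] <- NA
  }
  rownames(panel) <- NULL
  list(panel = panel, miss_ind = as.data.frame(miss_ind))
}

#' Write / read the long panel CSV dialect
#'
#' One row per person-wave; missing cells are written empty. Column order is
#' fixed: person_id, household_id, wave, income, housing_costs, n_adults,
#' n_children, gender, ethnicity, education, employment, benefits, tenure,
#' marital, region, age, sf12_pcs, sf12_mcs, ghq_score, ghq_case, a.
#'
#' @param panel panel data.frame.
#' @param path file path.
#' @return `write_panel` returns the path invisibly; `read_panel` the panel.
#' @export
write_panel <- function(panel, path) {
  cols <- c("person_id", "household_id", "wave", "income", "housing_costs",
            "n_adults", "n_children", "gender", "ethnicity", "education",
            "employment", "benefits", "tenure", "marital", "region", "age",
            "sf12_pcs", "sf12_mcs", "ghq_score", "ghq_case", "a")
  cols <- intersect(cols, names(panel))
  utils::write.csv(panel[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  utils::read.csv(path, na.strings = "")
}
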