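# Derivation: raw person-wave panel -> analysis table -------------------------

#' Equivalized after-housing-cost income
#'
#' Disposable income net of housing costs, scaled by the household
#' equivalence factor (modified-OECD by convention: 1.0 first adult, 0.5
#' each further adult, 0.3 per child). Negative values are retained: a
#' household can owe more in housing than it receives.
#'
#' @param income household income (currency/month).
#' @param housing_costs housing costs (currency/month).
#' @param equivalence_scale positive equivalence factor.
#' @return Numeric equivalized AHC income.
#' @export
equivalize_income <- function(income, housing_costs, equivalence_scale) {
  if (any(equivalence_scale <= 0, na.rm = TRUE))
    stop("equivalence_scale must be positive", call. = FALSE)
  (income - housing_costs) / equivalence_scale
}

#' Modified-OECD equivalence scale
#'
#' @param n_adults number of adults (>= 1).
#' @param n_children number of children under 14.
#' @return The scale: 1 + 0.5 (n_adults - 1) + 0.3 n_children.
#' @export
oecd_scale <- function(n_adults, n_children) {
  1 + 0.5 * (pmax(n_adults, 1) - 1) + 0.3 * n_children
}

#' Relative poverty line for one wave
#'
#' 60% of the median equivalized AHC income across person-wave rows of that
#' wave (person-weighted; even-count median is the mean of the two central
#' values).
#'
#' @param eq_income equivalized incomes of one wave (NAs dropped).
#' @return The threshold.
#' @export
poverty_line <- function(eq_income) {
  x <- eq_income[!is.na(eq_income)]
  if (length(x) == 0) stop("poverty_line: no non-missing incomes in wave",
                           call. = FALSE)
  0.6 * stats::median(x)
}

#' Derive the binary poverty exposure
#'
#' Adds `eq_income` and `a` columns: `a = 1` iff equivalized AHC income is
#' strictly below 60% of that wave's median (ties at the line are unexposed).
#' The line is recomputed within each wave.
#'
#' @param panel panel with income, housing_costs and either an
#'   `equivalence_scale` column or `n_adults`/`n_children`.
#' @return The panel with `eq_income` and `a` columns.
#' @export
derive_poverty <- function(panel) {
  scale <- if ("equivalence_scale" %in% names(panel)) panel$equivalence_scale
           else oecd_scale(panel$n_adults, panel$n_children)
  panel$eq_income <- equivalize_income(panel$income, panel$housing_costs, scale)
  line <- tapply(panel$eq_income, panel$wave,
                 function(x) if (all(is.na(x))) NA_real_ else poverty_line(x))
  panel$a <- as.integer(panel$eq_income < line[as.character(panel$wave)])
  panel
}

#' GHQ-12 caseness
#'
#' @param ghq_score integer score in [0, 12]; NA passes through.
#' @return 1 if score >= 4 (likely common mental disorder), else 0.
#' @export
derive_caseness <- function(ghq_score) {
  bad <- !is.na(ghq_score) & (ghq_score < 0 | ghq_score > 12)
  if (any(bad)) stop("ghq_score out of range [0, 12]", call. = FALSE)
  as.integer(ghq_score >= 4)
}

# covariates lagged by one wave in the adjustment set
.lagged_covariates <- c("a", "ghq_case", "employment", "benefits", "tenure",
                        "marital", "n_children", "region", "sf12_pcs",
                        "sf12_mcs")

#' Build the analysis table
#'
#' Joins each person-wave row (t) to the same person's row at t-1 on
#' consecutive observed waves, attaching the lagged adjustment set: prior
#' exposure and caseness, prior employment, benefits, tenure, marital
#' status, children, region, SF-12 components; employment enters at both t
#' and t-1. A skipped wave breaks the lag chain; each person's first
#' observed wave contributes only as a lag source. Rows with age outside
#' [25, 64] at time t are dropped (per wave, not per person). Adds `age2`
#' and a categorical `wave_f` marker.
#'
#' @param panel panel with `a` and `ghq_case` present (see
#'   [derive_poverty()], [derive_caseness()]).
#' @return The analysis table: one row per usable person-wave.
#' @export
build_analysis_table <- function(panel) {
  if (anyDuplicated(panel[, c("person_id", "wave")]))
    stop("duplicate (person_id, wave) rows", call. = FALSE)
  panel <- panel[order(panel$person_id, panel$wave), ]
  lagged <- intersect(.lagged_covariates, names(panel))
  prev <- panel[, c("person_id", "wave", lagged)]
  names(prev) <- c("person_id", "wave",
                   paste0(ifelse(lagged %in% c("a", "ghq_case"),
                                 sub("^a$", "a", sub("ghq_case", "y", lagged)),
                                 lagged), "_lag"))
  prev$wave <- prev$wave + 1L
  tab <- merge(panel, prev, by = c("person_id", "wave"))
  tab <- tab[!is.na(tab$age) & tab$age >= 25 & tab$age <= 64, ]
  tab$age2 <- tab$age^2
  tab$wave_f <- factor(tab$wave)
  tab <- tab[order(tab$person_id, tab$wave), ]
  rownames(tab) <- NULL
  tab
}

#' Restrict the analysis table to a transition estimand
#'
#' "into": rows not in poverty at t-1; exposure is becoming poor at t
#' (reference: not poor in both years). "outof": rows in poverty at t-1;
#' exposure is leaving poverty at t (reference: poor in both years).
#'
#' @param analysis_table from [build_analysis_table()].
#' @param estimand "into" or "outof".
#' @return The restricted table with an `exposure` column and an
#'   `estimand` attribute.
#' @export
derive_transitions <- function(analysis_table, estimand = c("into", "outof")) {
  estimand <- match.arg(estimand)
  if (estimand == "into") {
    tab <- analysis_table[!is.na(analysis_table$a_lag) & analysis_table$a_lag == 0, ]
    tab$exposure <- tab$a
  } else {
    tab <- analysis_table[!is.na(analysis_table$a_lag) & analysis_table$a_lag == 1, ]
    tab$exposure <- 1L - tab$a
  }
  rownames(tab) <- NULL
  attr(tab, "estimand") <- estimand
  tab
}
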