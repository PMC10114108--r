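# Conditional fixed-effects logistic comparator -------------------------------
#
# Chamberlain's conditional likelihood: conditioning each person's outcome
# sequence on its total eliminates the person-level intercept. The
# normalizing sum over all same-total sequences is computed by dynamic
# programming over (wave, running total) in log space, never by
# enumeration; the score uses the matching forward-backward recursion.

.logadd <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log1p(exp(pmin(a, b) - m)))
}

# forward DP: f[t+1, j+1] = log sum over subsets of items 1..t of size j
# of exp(sum eta)
.cond_forward <- function(eta) {
  tt <- length(eta)
  f <- matrix(-Inf, tt + 1L, tt + 1L)
  f[1L, 1L] <- 0
  for (t in seq_len(tt)) {
    f[t + 1L, 1L] <- f[t, 1L]
    j <- seq_len(t)
    f[t + 1L, j + 1L] <- .logadd(f[t, j + 1L], f[t, j] + eta[t])
  }
  f
}

#' Conditional log-likelihood contribution of one person
#'
#' log of exp(sum of eta over waves with y = 1) divided by the sum of the
#' same quantity over all outcome sequences with the same total. Concordant
#' sequences (all 0 or all 1) contribute 0 and are excluded from fitting.
#'
#' @param y person's binary outcome sequence (length T <= 30).
#' @param eta person's linear predictor sequence x_t' beta.
#' @return The log-likelihood contribution (scalar).
#' @export
conditional_loglik <- function(y, eta) {
  tt <- length(y)
  if (tt > 30L) stop("sequence longer than 30 waves", call. = FALSE)
  k <- sum(y)
  if (k == 0L || k == tt) return(0)
  f <- .cond_forward(eta)
  sum(eta[y == 1]) - f[tt + 1L, k + 1L]
}

# P(s_t = 1 | total = k) for all t, via forward/backward DP
.cond_prob_in <- function(eta, k) {
  tt <- length(eta)
  f <- .cond_forward(eta)
  b <- .cond_forward(rev(eta))   # backward = forward on reversed sequence
  denom <- f[tt + 1L, k + 1L]
  p <- numeric(tt)
  for (t in seq_len(tt)) {
    # items before t: 1..t-1 (forward row t), items after: t+1..T
    # (backward row tt - t + 1, i.e. last tt - t items)
    jmax <- min(t - 1L, k - 1L)
    js <- 0:jmax
    rem <- k - 1L - js
    ok <- rem >= 0L & rem <= (tt - t)
    if (!any(ok)) { p[t] <- 0; next }
    terms <- f[t, js[ok] + 1L] + b[tt - t + 1L, rem[ok] + 1L]
    m <- max(terms)
    p[t] <- exp(eta[t] + m + log(sum(exp(terms - m))) - denom)
  }
  p
}

#' Conditional fixed-effects logistic regression
#'
#' Fits the exposure effect (and optional time-varying covariates) by
#' maximizing the summed conditional log-likelihood over outcome-discordant
#' persons with a quasi-Newton optimizer and analytic DP score. Covariates
#' that are constant within every person are dropped (they cancel with the
#' fixed effect), as are time-invariant confounders by construction.
#'
#' @param analysis_table analysis table (see [build_analysis_table()]).
#' @param covariates extra model terms beyond the exposure (time-varying
#'   only; e.g. the lagged confounder set for the adjusted variant).
#' @param exposure_col,outcome_col column names.
#' @param tol gradient-norm convergence tolerance.
#' @return List of class `cond_logit_fit`: `coef`, `vcov` (inverse observed
#'   information), `or_` (exposure odds ratio), `loglik`,
#'   `n_informative`, `n_dropped` (concordant persons), `dropped_terms`,
#'   and `prob_contrast` -- the predicted-probability difference evaluated
#'   at fixed effect 0, an approximation reported with that caveat since
#'   absolute differences are not identified after conditioning.
#' @export
fit_conditional_logit <- function(analysis_table, covariates = character(),
                                  exposure_col = "a",
                                  outcome_col = "ghq_case",
                                  tol = 1e-8) {
  terms <- c(exposure_col, covariates)
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(fml, analysis_table)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  y <- analysis_table[[outcome_col]]
  pid <- analysis_table$person_id

  # drop columns constant within every person (not identified)
  within_var <- vapply(seq_len(ncol(X)), function(j) {
    max(tapply(X[, j], pid, function(v) max(v) - min(v)))
  }, 0)
  dropped_terms <- colnames(X)[within_var == 0]
  X <- X[, within_var > 0, drop = FALSE]
  if (!any(colnames(X) == exposure_col))
    stop("exposure has no within-person variation", call. = FALSE)

  groups <- split(seq_len(nrow(X)), pid)
  ksum <- vapply(groups, function(i) sum(y[i]), 0)
  tlen <- lengths(groups)
  informative <- ksum > 0 & ksum < tlen
  if (!any(informative))
    stop("no outcome-discordant individuals", call. = FALSE)
  g_inf <- groups[informative]

  negll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(vapply(g_inf, function(i) conditional_loglik(y[i], eta[i]), 0))
  }
  neggr <- function(beta) {
    eta <- drop(X %*% beta)
    g <- numeric(ncol(X))
    for (i in g_inf) {
      p <- .cond_prob_in(eta[i], sum(y[i]))
      g <- g + colSums(X[i, , drop = FALSE] * (y[i] - p))
    }
    -g
  }
  opt <- stats::optim(numeric(ncol(X)), negll, neggr, method = "BFGS",
                      hessian = TRUE,
                      control = list(maxit = 200, reltol = 1e-12))
  gn <- sqrt(sum(neggr(opt$par)^2))
  if (!is.finite(opt$value) || any(abs(opt$par) > 30))
    stop("conditional logit did not converge (possible separation)",
         call. = FALSE)
  if (gn > max(tol, 1e-4 * (1 + abs(opt$value))))
    warning("gradient norm ", format(gn), " above tolerance at optimum")
  vcov <- tryCatch(solve(opt$hessian), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  beta <- stats::setNames(opt$par, colnames(X))

  # probability contrast at fixed effect = 0 (approximation, see docs)
  eta1 <- drop(X %*% beta) + (1 - X[, exposure_col]) * beta[exposure_col]
  eta0 <- drop(X %*% beta) - X[, exposure_col] * beta[exposure_col]
  prob_contrast <- 100 * mean(expit(eta1) - expit(eta0))

  structure(list(coef = beta, vcov = vcov,
                 or_ = unname(exp(beta[exposure_col])),
                 loglik = -opt$value,
                 n_informative = sum(informative),
                 n_dropped = sum(!informative),
                 dropped_terms = dropped_terms,
                 prob_contrast = prob_contrast),
            class = "cond_logit_fit")
}
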