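---
title: "Estimating the short-term effect of poverty on common mental disorder with marginal structural models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the short-term effect of poverty on common mental disorder with marginal structural models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Household income poverty and common mental disorder (CMD) are entangled in
both directions. Poverty plausibly causes psychological distress; but poor
mental health also lowers earnings capacity, a feedback known as *health
selection*, and the two share time-varying causes (employment, benefit
receipt, housing tenure, family structure, physical health) that are
themselves affected by earlier poverty and earlier distress. Conventional
regression adjustment for such intermediate confounders blocks part of the
causal pathway of interest and can bias the estimate in either direction.

`povertymsm` implements the standard epidemiological answer to this
structure: a **marginal structural model** (MSM) fitted with **stabilized
inverse-probability-of-treatment weights** (IPTW) and a double-robust
outcome model, applied to annual panel data in long person-wave format.

The exposure $A_t$ is relative income poverty: household equivalized income
after housing costs below 60% of the contemporaneous within-sample median
(strict inequality; ties at the line are unexposed). Equivalization uses
the modified-OECD scale (1.0 first adult, 0.5 further adults, 0.3 per
child). The outcome $Y_t$ is GHQ-12 "caseness", a score of 4 or more on the
12-item General Health Questionnaire.

The estimand is the *short-term* causal risk difference at each wave,

$$\mathrm{RD} = E\{P(Y_t = 1 \mid A_t = 1, W_t) - P(Y_t = 1 \mid A_t = 0, W_t)\},$$

conditional only on the preceding year's exposure status — not the effect
of persistent poverty. The adjustment set $W_t$ follows the causal diagram
of this design: all time-invariant confounders (gender, ethnicity,
education); all time-varying confounders at $t-1$ (benefits, tenure,
marital status, children, region, SF-12 physical and mental components,
prior caseness, prior poverty); employment at both $t$ and $t-1$ (income
responds to job change faster than jobs respond to income); age and age
squared; and a categorical wave marker for secular trend.

## The estimator

1. **Exposure model.** Pooled logistic regression of $A_t$ on the full
   adjustment set (the *denominator*), and of $A_t$ on the wave marker
   alone (the *numerator*). Each row receives the stabilized weight
   $sw = \hat P_{num}(A_t = a_{obs}) / \hat P_{den}(A_t = a_{obs})$.
2. **Balance diagnostics.** Standardized mean differences (SMD) between
   exposure groups, before and after weighting, for every indicator-expanded
   covariate; $|SMD| < 0.1$ is treated as negligible and $< 0.2$ as
   acceptable, the conventional thresholds.
3. **Outcome model.** Weighted pooled logistic regression of $Y_t$ on
   $A_t$ *and the same covariates* (double robust: consistency requires
   only one of the two models to be correct).
4. **Standardization.** Every row is predicted with $A_t$ forced to 1 and
   to 0; the weighted averages of these predictions give the marginal risk
   difference (in percentage points), the counterfactual prevalence in the
   unexposed, and the population attributable fraction
   $\mathrm{PAF} = 100\,(\text{prev}_{total} - \text{prev}_{unexposed})/\text{prev}_{total}$.
   The odds ratio is taken from the exposure coefficient — a conditional
   OR; the marginal counterfactual prevalences are reported alongside so
   the non-collapsibility gap is visible.
5. **Uncertainty.** A person-level cluster bootstrap re-runs weighting and
   estimation on resampled *persons* (all their waves), respecting
   within-person correlation. Standard errors are the SD of replicates;
   default CIs are normal ($\pm 1.96\,se$), matching the "bootstrapped
   standard errors" convention; percentile CIs are available.

Transition estimands restrict the sample per the at-risk reference groups:
*moves into poverty* compares new poverty ($A_{t-1}=0, A_t=1$) against
staying out of poverty, and *moves out of poverty* compares exits
($A_{t-1}=1, A_t=0$) against staying poor — with the weights refit on each
restricted sample and the now-constant lagged-exposure term removed.
Stratified analyses (gender, education, age dichotomized at 40/41) refit
the weights within each stratum and drop the stratifier from the
covariate sets.

### Why the stabilization numerator is the wave marker only

A common choice places prior exposure in the numerator,
$P(A_t \mid A_{t-1}, \text{wave})$. That shrinks weight variability but,
by construction, leaves the marginal association between $A_{t-1}$ and
$A_t$ in the pseudo-population: prior poverty can then never reach
$|SMD| < 0.1$. Because this package treats lagged poverty as one of the
confounders whose balance is asserted (and because applied analyses of
this design report prior poverty balanced alongside the rest), the default
numerator is the wave marker alone. The cost is heavier weight tails
(the 99th percentile is around 7 in the default scenario); `truncation`
in `exposure_spec()` offers optional percentile clamping, off by default
since the weights remain well behaved (mean within 0.01 of 1).

## The synthetic panel generator

No restricted-access survey data ship with the package. Instead
`generate_panel()` draws panels with the statistical structure the
analysis assumes, and `compute_oracle_truth()` supplies the ground truth
that makes estimator validation possible:

* time-invariant confounders: gender (50% women), ethnicity (14%
  non-White), education in three levels (35/45/20% high/medium/low);
* time-varying confounders drawn given the previous wave's state:
  employment (persistent, education-dependent, reduced by prior CMD),
  benefit receipt, housing tenure, marital status, children, SF-12
  physical score with AR dynamics; age advances one year per wave with
  per-wave eligibility at 25-64;
* log household income: covariate-dependent mean (employment +0.85,
  education ±0.28 per level, physical health) with AR(1) persistence
  (ρ = 0.4), *logistic* innovations (SD 0.45), plus **health selection** —
  prior caseness shifts log income by the `selection_effect` (−0.35 by
  default, −1.2 in the `strong_selection` preset);
* a deterministic partner-income multiplier (1.6) when coupled, housing
  costs as a noisy 28% income share, and the modified-OECD scale, so the
  derived poverty indicator responds to household composition;
* CMD caseness from a latent logit: intercept −1.45, current poverty
  `exposure_effect` (0.15), optional onset-specific surplus
  (`onset_effect`), prior caseness (+1.1, state dependence), and the
  confounder coefficients listed in `?sim_config`; the GHQ-12 score is
  emitted consistently with caseness (score ≥ 4 iff case);
* missing-at-random cell missingness whose logit depends on observed
  employment, gender and age, with the intercept calibrated so the
  realized rate matches the configured one (8% by default), and monotone
  per-wave attrition (4%).

The income spread, baseline logit and exposure coefficient were calibrated
once so the default scenario resembles the UK working-age panel this
design targets — roughly 22-26% poverty prevalence, 19-20% CMD prevalence,
an oracle risk difference near 2.1 percentage points and a marginal odds
ratio near 1.14 — and then frozen; tests treat them as fixed study
conditions, not tuning knobs.

The oracle evaluates, at every analysis wave of a large natural-course
simulation, each person's outcome probability with exposure forced to 1
and to 0 (history untouched), so `true_rd` is exactly the estimand the MSM
targets; restricted averages over rows with lagged exposure 0 or 1 give
the transition truths on the same reference populations the estimators
use. Logistic income innovations make the true exposure model close to a
logistic regression in the adjustment set, so the "correct weights" arm
of the double-robustness property is attainable; the outcome model is
logistic in the adjustment set by construction.

What the generator does **not** emulate — and what passing tests therefore
cannot certify — includes: survey design (clustering, stratification,
longitudinal weights), item-level GHQ-12/SF-12 measurement, real
geography, income measurement error, non-monotone attrition, and
not-at-random missingness. Results on real survey data depend on those
features and on the no-unmeasured-confounding assumption, which no
synthetic benchmark can verify.

## Multiple imputation

`mice_impute()` is a chained-equations engine with regression draws:
linear fits plus residual-scale noise for continuous variables, Bernoulli
draws from logistic fits for binary ones, sequential logistic draws for
ordinal education. Income is imputed on the log scale; products of income
with the three effect modifiers (gender, education, age) enter the
imputation designs; exposure and outcome are *re-derived* after imputation
from the imputed income and GHQ score rather than imputed directly. Rows
missing more than 9 of the declared analysis variables (22 in the full
protocol; configurable) are excluded first. Variables cycle in ascending
order of missingness for a fixed 10 iterations with a per-variable
convergence trace — chosen over a formal stopping rule for determinism
and simplicity; the trace is exposed for inspection. Predictive mean
matching is a noted extension, not implemented; regression draws are
adequate for the synthetic data the engine is validated on. Estimates
from the `m = 20` (default) completed datasets are pooled by Rubin's
rules, with bootstrap variances computed within each dataset.

## Conditional fixed-effects comparator

`fit_conditional_logit()` implements the conditional likelihood that
eliminates person-level intercepts by conditioning each person's outcome
sequence on its total. The normalizing sum over same-total sequences is
computed by dynamic programming over (wave, running total) in log space —
never by enumeration — with an analytic forward-backward score; a
quasi-Newton optimizer (gradient tolerance $10^{-8}$) maximizes the summed
likelihood over outcome-discordant persons. Absolute probability
differences are *not identified* after conditioning; the comparator
reports the odds ratio as primary and a probability contrast evaluated at
fixed effect zero, explicitly labelled an approximation. On panels with
strong health selection the unadjusted conditional-logit estimate diverges
sharply from the MSM (it can even flip sign), while adding the lagged
confounders brings it close — the methodological contrast this comparator
exists to exhibit.

## Numerical choices and edge cases

* Even-count medians are the mean of the central pair; the poverty line is
  person-weighted within wave.
* Lags require *consecutive* observed waves; a skipped wave breaks the lag
  chain rather than bridging the gap, since wave spacing is handled by the
  age covariate.
* Perfect separation in any logistic fit is an error naming the worst
  covariate; collinear columns are dropped with a warning.
* Fitted exposure probabilities below $10^{-6}$ raise a positivity error
  listing the offending rows instead of silently producing huge weights.
* Zero-variance covariates yield SMD 0 when means agree and signed
  infinity (flagged) otherwise.
* Bootstrap replicates that fail (e.g. separation in a resample) are
  dropped and counted; more than 10% failures aborts. Inner bootstrap
  refits use a Cholesky-based IRLS warm-started at the full-sample
  coefficients, falling back to `glm.fit` on singular designs.
* All randomness is seeded; stage seeds derive from the global seed by a
  stable hash of the stage name, so configuring an extra pipeline stage
  never changes another stage's draws.

## Validation summary

The test suite validates each stage against an independent oracle:
deterministic identities (PAF formula, weight ratio, caseness boundary,
transition partition), closed forms (discordant-pair likelihood, Rubin
fixtures, contingency-table standardization), brute-force enumeration
(DP conditional likelihood, integer-weight SMD replication), and
simulation benchmarks (oracle recovery of the risk difference over 50
replicates at n = 5000 persons x 6 waves; 95% bootstrap CI coverage under
a null effect over 200 replicates at n = 1500 x 4 with 100 bootstrap
draws; double-robustness arms at n = 4000 x 5; MI-versus-complete-case
repair over 20 replicates). Problem sizes were chosen so Monte-Carlo
error is small relative to the effects being detected while the whole
suite runs on a single CPU.
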