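# povertymsm

Causal estimation of the short-term effect of household income poverty on
common mental disorder (CMD) in annual panel data, for epidemiologists and
social scientists working with long person-wave tables (UKHLS-style
cohorts).

Poverty and mental health confound each other in time: employment, benefit
receipt, tenure and family structure drive both, and poor mental health
itself lowers subsequent income (*health selection*). Plain regression on
such data adjusts away part of the effect or leaves reverse causation in.
`povertymsm` implements the standard causal answer — a **double-robust
marginal structural model**:

- exposure `A_t`: equivalized after-housing-cost household income below
  60% of that wave's median (modified-OECD scale, strict threshold);
- outcome `Y_t`: GHQ-12 caseness (score >= 4);
- estimand: the short-term causal risk difference
  `E{P(Y=1|A=1,W) - P(Y=1|A=0,W)}` with `W` the lagged confounder
  adjustment set (plus employment at t and the wave marker);
- estimator: stabilized IPTW from a pooled logistic exposure model,
  SMD balance diagnostics, a weighted covariate-adjusted outcome model,
  and g-computation standardization; person-level cluster bootstrap for
  uncertainty; population attributable fractions
  `PAF = 100 (prev_total - prev_unexposed) / prev_total`;
- transition estimands (moves **into** vs **out of** poverty, with the
  at-risk reference-group restrictions), stratified effects (gender,
  education, age 25-40 vs 41-64);
- chained-equations multiple imputation with Rubin's-rules pooling;
- a conditional fixed-effects logit comparator (dynamic-programming
  Chamberlain likelihood);
- a synthetic panel generator with counterfactual oracle truth, so the
  whole pipeline is testable without restricted survey data.

## Worked example

```r
library(povertymsm)

cfg  <- sim_config(n_individuals = 12000, n_waves = 6, seed = 1,
                   missingness = list(rate = 0), attrition_rate = 0)
panel <- derive_poverty(generate_panel(cfg))
tab   <- build_analysis_table(panel)

esp   <- exposure_spec(numerator = "wave_f")
truth <- compute_oracle_truth(cfg, n_mc = 100000)
ws    <- compute_stabilized_weights(tab, esp)
est   <- bootstrap_estimate(tab, esp, n_replicates = 200, seed = 2)

c(oracle_rd = truth$true_rd, msm_rd = est$rd, se = est$se$rd,
  or = est$or_, paf = est$paf)
```

On one run of this scenario the package printed (percentage points unless
noted):

```
poverty prevalence 25.6%   CMD prevalence 19.2%
oracle RD 2.14             MSM RD 1.92 (bootstrap SE 0.66)
odds ratio 1.14            PAF 2.4%
into-poverty RD  1.60      (oracle 1.96)
out-of-poverty RD -2.61    (oracle -2.67)
max weighted |SMD| 0.037   (unweighted max 1.48)
```

Reading: before weighting the exposed and unexposed differ grossly
(employment SMD above 1); after weighting every adjusted covariate is
balanced below the 0.1 negligibility threshold, and the weighted,
covariate-adjusted estimate recovers the counterfactual oracle within its
bootstrap standard error. Moving into poverty raises CMD prevalence by
about 2 points; moving out lowers it by a slightly larger amount in this
generative scenario because baseline risk is higher among the previously
poor. `balance_table()` / `plot_balance()` produce the love plot,
`estimate_stratified()` the stratum effects, `fit_conditional_logit()` the
fixed-effects comparison, and `run_pipeline()` orchestrates all stages
(simulate, derive, impute, weight, estimate, transitions, strata,
fe-compare, report) with per-stage seeds and CSV/JSON outputs.

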