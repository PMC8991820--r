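---
title: "Handling missing cost and quality-of-life data in within-trial cost-effectiveness analysis"
author: "ceamiss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handling missing cost and quality-of-life data in within-trial cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A within-trial cost-effectiveness analysis needs, for every patient, a
discounted total cost and a total quality-adjusted life year (QALY) count up
to some horizon. Long trials with staggered recruitment and a fixed calendar
end date cannot deliver that: a patient recruited late is administratively
censored early, and budget-limited follow-up (here, a single late
"telephone" assessment) leaves most of the late utility grid unobserved.
Item non-response adds a second, stochastic layer. Any estimate of the
incremental cost ΔC and incremental QALYs ΔQ therefore embeds a model of
the missing data, and different models can move both the point estimates
and, especially, the standard errors.

`ceamiss` implements six estimation strategies around a common regression
specification, together with a synthetic-trial generator that reproduces
the design-driven missingness pattern, so that each estimator can be tested
against a known truth.

## Trial design emulated by the generator

The generator (`trial_config()`, `generate_complete()`,
`impose_missingness()`) emulates a two-arm venous-leg-ulcer trial:

* **450 patients**, allocated 1:1, recruited uniformly over **36 months**,
  study closing at month **65** after first recruitment; follow-up is
  therefore 29–65 months (median 47). A 12-month minimum follow-up is not
  enforced: it is inconsistent with the recruitment window and study end,
  and we keep the dates.
* **Cost periods**: weeks {0,4,8,13,17,22,26,30,35,39,43,48,52,104,156,
  208,260} — 12 roughly monthly periods in year 1, then 4 yearly periods.
  Intra-year boundaries are chosen for near-equal spacing; only the
  period count and the year-1/yearly split are fixed by the design.
* **EQ-5D** utility at weeks {0, 6, 26, 52} plus at most one late
  follow-up: the latest grid week in {104, 156, 208, 260} not exceeding the
  patient's censoring week (the *telephone rule*).
* **Outcomes** follow a linear model: a period/week intercept profile,
  centred baseline covariates (age, ulcer size, ulcer duration, site as a
  fixed factor), a treatment-by-time interaction, a shared per-patient
  intercept, and independent normal residuals. Costs are floored at zero
  after noise; utilities are clamped to [−0.594, 1]. Both event rates are
  reported as attributes; the default levels and spreads are chosen so that
  clamping is rare (≈0.5% of utilities) and the configured effects survive
  essentially unchanged.
* **Deaths** are optional exponential times (off by default); a patient who
  dies keeps zero cost and zero utility thereafter — death creates no
  missingness.
* **Item missingness** is logistic in treatment, centred covariates, site,
  time in follow-up, and optionally the most recent *still observed*
  utility. Because the sweep over weeks is sequential, the outcome-history
  term conditions only on observed data, so the mechanism is MAR by
  construction. Baseline data are never missing.

Defaults encode the reference scenario used throughout validation: **zero
incremental cost in every period** and a **constant post-baseline utility
effect solved so the undiscounted 3-year incremental QALY is exactly
0.07** (the constant is 0.07·52/153 ≈ 0.0238; the 1-year share is
0.07·49/153 ≈ 0.0224 and the 5-year total 0.07·257/153 ≈ 0.1176).

The complete pre-masking tables are retained in a shadow slot for recovery
testing; estimators never read it.

What the generator does **not** emulate: the real accrual curve (recruitment
is uniform, so the follow-up distribution differs from any particular
trial), heavy-tailed cost distributions (costs are floored normals, not
log-normal or zero-inflated), item-level EQ-5D responses and tariff
valuation (utilities enter as already-valued indices), and resource-use
micro-costing. Passing tests therefore show correctness of the estimators
under a normal, MAR, randomised world — not robustness to skewness or MNAR.

## Outcome construction

`discount_factor()` discounts by completed year at the interval midpoint
(year-1 items undiscounted); the rate defaults to 3.5%/year. Whether QALYs
should be discounted alongside costs is left configurable
(`qaly_rate`), and the validation work reports QALYs undiscounted so they
are comparable with the generator's nominal truth.

`total_cost()` sums discounted period costs and is missing if **any**
period in the horizon is missing — a cost integral cannot skip a period.
`qaly_trapezium()` integrates the utility curve linearly between the
patient's *scheduled* weeks. Under the telephone rule a patient's schedule
after year 1 contains a single week, so a late segment may span several
years; the total at horizon T is computable only when week 52·T itself is a
scheduled, observed point and nothing earlier in the schedule is missing.
This per-patient-schedule reading is what makes a nonzero complete-case
count possible at 3 and 5 years at all (a full-grid reading would make
every patient incomplete past year 1, since the design schedules at most
one late week). Weeks pruned by the telephone rule are *not part of the
schedule* and so do not render a patient incomplete; item non-response at a
scheduled week does. Segments never straddle the horizon because the
horizon must itself be a grid point.

## The six estimators

All share the regression vocabulary of the trial: treatment, centred
duration, age and size, site as a fixed factor, and (for aggregate models)
baseline EQ-5D.

**CCA** (`cca_fit()`): drop every patient with an incomplete total, then a
bivariate normal regression of (total cost, total QALY) on the shared
regressors. With identical regressors in both equations the
seemingly-unrelated-regressions estimator collapses to per-equation least
squares, and the joint covariance is the Kronecker product of the 2×2
residual covariance with the shared inverse Gram matrix — this identity is
enforced by test against per-equation OLS at 10⁻¹⁰. Valid only if
completeness is ignorable given covariates; wasteful by construction.

**MILR / MIPMM** (`mice_impute()`, `mi_fit()`): chained equations on the
patient-level wide layout (16 period costs + 7 post-baseline utilities).
Variables are visited in schedule order, earliest first; each incomplete
variable is regressed on all other longitudinal variables plus the baseline
predictors (treatment, age, duration, site, ulcer size, ethnicity,
diabetes, DVT history, trial leg, baseline EQ-5D). The linear imputer is
*proper*: residual variance drawn from its scaled inverse-χ² posterior,
coefficients from their conditional normal, plus residual noise. PMM uses
type-2 matching — posterior-draw predictions for incomplete cases,
least-squares predictions for donors — with 10 donors by default and all
ties at the k-th distance included. Cells missing by design are imputed
too: that is precisely how imputation recovers horizons beyond an
individual's follow-up, and why MI keeps all 450 patients at every horizon.
Totals are then built passively per completed dataset, the bivariate
regression run on each, and results pooled by Rubin's rules with
Barnard–Rubin degrees of freedom; the FMI uses those degrees of freedom,
and the Monte-Carlo error of the pooled estimate is √(B/M). Per-imputation
seeds are `seed + m·1009`, so runs are reproducible and independent.
Defaults M = 40, 20 cycles.

**RMM / RMFE** (`fit_rmm()`, `fit_rmfe()`): the long-format repeated-
measures model — outcome on covariates, week (factor, baseline reference)
and treatment-by-week interaction — with the patient intercept treated as a
random effect (REML via `lme4`; ML by flag) or eliminated by the within
transform (subject-demeaned least squares, cluster-robust covariance by
patient). For the cost model every patient contributes a week-0 row equal
to zero, so the interaction at week t is directly the incremental cost of
period t; for EQ-5D the week-0 row is the observed baseline utility and the
arm difference at week t is the treatment main effect plus the interaction.
Totals are linear combinations: discounted sums of interaction
coefficients for costs, trapezium weights for QALYs (for the within
estimator the absorbed main effect enters as zero — randomisation). Their
variances are the corresponding quadratic forms of the coefficient
covariance. CEA uncertainty uses a cluster bootstrap, resampling patients
with replacement stratified by arm (clustering is forced by repeated
measures; stratification preserves arm sizes); both outcome models are
refit on the same resample so the cost–QALY correlation is captured.
Failed replicates are redrawn and counted; more than 5% aborts.

**BPA** (`bpa_fit()`): the Bayesian selection model on aggregate totals.
Outcomes are bivariate normal given the shared regressors
(parameterised as a marginal cost equation plus a conditional QALY
equation, so the marginal treatment coefficients are read off directly);
every missing total is a stochastic node drawn from its conditional normal
given the observed partner outcome and the parameters
(`conditional_outcome_moments()` states the closed form the sampler must
respect, and a test checks it). Logistic submodels of the two missingness
indicators — with follow-up length as an additional covariate — complete
the selection factorisation. Under MAR with distinct priors they cannot
move the outcome posterior; a flag disables them and a test verifies the
posterior is unchanged. Sampling is MCMC through JAGS with 2 chains
(10,000 kept / 2,000 burn-in by default) and a split-chain
scale-reduction gate at 1.05. Outcomes and covariates are standardized
inside the sampler so the coefficient-prior precision (default 0.001,
varied to 0.01 in sensitivity analyses) is vague regardless of the GBP
scale; residual precisions get Gamma(0.01, 0.01). Placing the varied
precision on the coefficient priors of the standardized outcome equations
is our resolution of an ambiguity in how such priors are usually reported;
the residual-precision reading is covered by the vague Gamma hyperprior.

**Reporting** (`icer()`, `ceac_parametric()`, `ceac_bootstrap()`,
`compare_methods()`): ICERs carry dominance labels rather than signed
ratios (a negative ratio from a dominant quadrant is meaningless); the
parametric CEAC is Φ((λμ_Q−μ_C)/√(λ²σ²_Q−2λσ_CQ+σ²_C)) on a £0–£50,000
grid in £500 steps, the bootstrap CEAC the fraction of draws with positive
net benefit. Parametric methods get normal-theory CIs, bootstrap methods
percentile CIs. `compare_methods()` runs everything from one master seed
and records per-method failures without aborting.

## Numerical choices and degenerate inputs

* Rank-deficient imputation or aggregate designs: aliased columns are
  dropped (imputation) or named in the error (aggregate fits). The within
  estimator drops interaction columns that the unbalanced panel cannot
  identify and reports them as absorbed.
* Quasi-separation in the missingness logit is detected (fitted
  probabilities at 0/1 or exploding coefficients) and reported with a
  warning rather than penalised — the diagnostic model is an ordinary
  logit.
* PMM donor ties at the k-th distance are all included; every imputed value
  is a member of the observed support by construction.
* `rubin_pool()` with identical estimates yields B = 0, T = W, zero MCE,
  infinite df (classic large-sample limit when `nu_com = Inf`).
* Zero net-benefit variance in the CEAC falls back to 0/1 by the sign of
  the mean (½ at exactly zero).
* All randomness flows from explicit integer seeds: generation from
  `config$seed`, masking from a derived seed, per-imputation seeds by a
  counter, per-chain JAGS RNG seeds derived from the sampler seed.

## Problem sizes used in validation

The shipped test-suite runs the estimator identities on 30-patient panels
(10–50 replicates), complete-data concordance of all six methods on one
450-patient trial, recovery on 25 independent 450-patient MAR trials
(MI at M = 8 / 5 cycles; MCMC at 2×2,000 with 500 burn-in), the
selection-bias demonstration on 16 trials, and the MI stability
diagnostics at the full M = 40 / 20 cycles. The `analysis/` scripts run the
full-scale comparison (M = 40, B = 500, 10k MCMC iterations). Coverage
checks for the panel estimators use the linear-combination variance rather
than the bootstrap, which remains the CEA-uncertainty route.

The selection-bias mechanism (`prev_utility_treat = −12` with intercept
−2.3 on the EQ-5D stream) was designed by a power calculation before the
corresponding test was frozen: it produces roughly an eight
Monte-Carlo-SE deviation for complete-case analysis at 16 replicates while
PMM imputation stays within the Monte-Carlo band.

## Known limitations

Under the single-telephone design the late utility weeks are *never
co-observed*: a patient contributes week 104 or week 156, not both, so the
chained-equation regressions linking them lean on values imputed in
earlier sweeps, and the late donor pools are small (tens of patients of
450). In this regime multiple imputation — predictive mean matching more
than the linear imputer — can attenuate the late-horizon QALY effect
relative to the complete-data estimator in some realisations; this is the
sparse-donor caution of the PMM literature materialising, and the
repeated-trial recovery checks bound it rather than eliminate it. The
acceptance script reports the paired complete-data estimate next to the
imputation estimate so the two sources of deviation are separable.

Costs are modelled and imputed on the raw scale and discounted passively.
Normality is assumed everywhere the estimators assume it; with genuinely
skewed costs the bootstrap-based methods are the safer uncertainty route.
Site enters all models as a fixed factor; random site effects and
three-level (site-clustered) imputation are out of scope, as are MNAR
sensitivity models — the missingness term never depends on the unobserved
value itself. The generator's five sites are fewer than a large multicentre
trial would have; a 20-level fixed factor would make the small
complete-case designs at late horizons singular, which is a property of
complete-case analysis worth noting in itself.
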