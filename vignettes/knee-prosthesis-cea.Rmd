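---
title: "Methods: lifetime cost-effectiveness of knee prosthesis brands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifetime cost-effectiveness of knee prosthesis brands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the decision model
and its assumptions, the statistical estimators that feed it, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## The decision problem

Five cemented, unconstrained, fixed-bearing total knee replacement (TKR)
prosthesis brands — PFC Sigma, AGC Biomet, Nexgen, Genesis 2 and Triathlon
— differ in purchase price, in case-mix-adjusted quality of life (QOL) six
months after surgery, and in long-term revision risk. The package estimates
which brand buys the most health per pound over a patient's remaining
lifetime, for men and women undergoing surgery at ages 60, 70 and 80.

## The Markov cohort model

`run_cohort()` simulates a hypothetical cohort through four health states —
*primary TKR*, *revision year*, *post-revision* and *dead* — with an annual
cycle over 45 cycles, which exhausts the lifetime of every cohort
considered (the life table absorbs all survivors by age 110).

* Cycle 0 applies operative mortality (brand-independent, default 0.002)
  and the initial cost: prosthesis price + £2 022 theatre + length of stay
  × £332 per bed day. Prices and the length-of-stay values per brand and
  sex are fixed reference inputs (`brand_reference()`); the length-of-stay
  values are defined as (published initial cost − price − £2 022)/£332, so
  cost assembly reproduces the published initial costs exactly.
* Each later cycle applies, in order: death at the life-table probability
  for the attained age times the healthy-patient relative risk; then first
  revisions from the primary state at the spline-model annual probability;
  then re-revisions. The revision-year state lasts exactly one cycle. Its
  survivors move to the post-revision state, whose first year carries the
  year-1 re-revision probability and later years the subsequent-years
  probability; re-revision cycles are unlimited (the published state
  diagram does not bound them, and bounding them would understate costs).
* QALYs accrue as occupancy × state utility, discounted at 3.5% per year;
  every utility declines with age by `aging_decline(a) = 0.004 (a/70)^2`
  per cycle (anchored so the reduction is 0.004 at age 70), floored at the
  EQ-5D-3L minimum of −0.594. Costs accrue £8 429 per revision episode in
  the cycle it occurs, discounted identically. No half-cycle correction is
  applied: the arithmetic is transparent and reproducible bit for bit, and
  the correction would cancel almost completely from incremental results.

The engine is validated against an independent individual-level
microsimulation of 100 000 patients (test suite) and against closed forms:
with unit utility, no deaths, no revisions and no aging decline, discounted
QALYs equal the 45-term annuity `(1 − 1.035^{-45})/(1 − 1/1.035)` = 23.283.

## QOL estimation

Post-operative EQ-5D-3L is regressed (OLS) on brand, sex, age, BMI,
comorbidity count, ASA grade, deprivation quintile, patella replacement,
disability and surgical-position flags, pre-operative EQ-5D-3L and Oxford
Knee Score, and two provider characteristics (consultant-led surgery,
independent-sector treatment centre). AGC Biomet — the cheapest brand and
the ICER base — is the reference level. The OKS is modelled in parallel for
reporting only; the decision model consumes EQ-5D-3L.

Continuous covariates are offered fractional-polynomial transforms
(`select_fractional_polynomial()`): powers from {−2, −1, −0.5, 0 (log),
0.5, 1, 2, 3}, first- or second-degree, adopted only when the Gaussian
deviance improves on both the linear and the quadratic fit by more than
4.605 (the conventional 0.10-level chi-square on 2 df; the source analysis
states no threshold).

Missing post-operative questionnaires (17% of patients) are multiply
imputed by chained equations (`impute_chained()`): proper Bayesian linear
draws for continuous columns, logistic for binary, 10 cycles per
imputation, m = 20 imputations, pooled by Rubin's rules (means across
imputations; within-variance plus (1 + 1/m) × between-variance).

QOL in the revision-year and post-revision states comes from separate
age-and-sex regressions on records collected before and six months after a
revision operation.

Subgroup predictions (`predict_subgroup_qol()`) set brand, sex and age and
hold every other covariate at its observed mean (factor levels at their
observed shares).

## Revision and re-revision risk

First-revision risk is a flexible parametric (Royston–Parmar) model: the
log cumulative hazard is a restricted cubic spline in log time plus linear
covariate effects (sex, age, ASA 3, BMI, patella replacement, antibiotic
cement, provider flags), fitted per brand via `flexsurv::flexsurvspline`
with `scale = "hazard"`. The cumulative-hazard (rather than hazard) scale
is the standard realization that supports extrapolation: beyond the
boundary knots the restricted spline continues linearly in log time.
Default internal knots: three, at the 10th/50th/90th percentiles of
uncensored log event times. Annual transition probabilities are
`p_t = (S(t−1) − S(t))/S(t−1)`.

Re-revision risk uses a two-piece constant hazard (first year after
revision vs all later years), estimated as events over person-years.
The piecewise sensitivity scenario replaces the spline with a piecewise
exponential on integer-year cuts (carried forward beyond the last cut),
fitted per brand and sex; the cut scheme is this package's choice since
the source analysis does not state one.

## Mortality

Background mortality is a Gompertz life table
`q(a) = 1 − exp(−B e^{0.10 a})` with sex-specific `B` calibrated once so
remaining life expectancy at 70 is 14 years (men) and 16 years (women);
any life table can be substituted via CSV (`read_life_table()`). The
healthy-patient effect multiplies `q` by
`RR(t) = 1 − (1 − RR0) exp(−t/2.35)` with
`RR0(a) = 1 − 0.7 (a − 40)/40` clamped to [0.3, 1]. Only one point of this
schedule is anchored by evidence (RR = 0.3 for men aged 80 in the year
after surgery, decaying to 1 over a decade); the linear-in-age form with a
floor, shared across sexes, is the simplest schedule consistent with the
effect being largest for older patients, and τ = 2.35 years puts RR(10)
above 0.99.

## Probabilistic analysis

`run_psa()` samples, per draw: the QOL coefficient vector (multivariate
normal from the Rubin-pooled covariance), the revision-state coefficient
vectors, each brand's spline parameters (multivariate normal from the
fitted covariance), and the re-revision rates (log-normal from their
asymptotic standard errors). Unit costs, prosthesis prices and the life
table are fixed — prices are contract values without sampling error.
Parameters estimated on different datasets are sampled independently.
Non-positive-definite covariances are repaired by eigenvalue flooring with
a logged message. Each draw runs the Markov model for all five brands;
1 000 draws by default.

From the draws: net monetary benefit `λ·QALYs − cost`; the ICER ladder
(`icer_ladder()`) sorts by mean cost, removes strictly and extendedly
dominated brands, and reports ICERs between successive frontier members
(extended dominance is implemented even though the published table reports
only simple dominance — a correct ladder requires it); the acceptability
frontier reports, per willingness-to-pay value (£0–£50 000 in £500 steps),
the brand with the highest mean NMB and the fraction of draws in which it
is optimal.

Five scenario analyses (`run_scenario()`): (1) brand QOL differences last
one year only — from cycle 1 every brand follows the across-brand mean
utility profile; (2) brand × age and brand × sex interactions in the QOL
model; (3) pre-operative EQ-5D-3L entered as quintile dummies — the
synthetic schema carries a continuous index rather than dimension-level
responses, so quintile indicators are the faithful categorical analogue;
(4) piecewise-constant revision hazards; (5) all brands priced at the mean
of the five prices (£1 456).

## The synthetic registry

No real registry extract is distributed; `cmd_simulate()` generates one
with known truth (`SyntheticTruth` is serialized beside every dataset so
parameter recovery is testable).

What it emulates:

* a QOL cohort of 53 126 patients, revision follow-up for 239 945, and
  54 134 re-revision records, with per-brand case-mix marginals (age, sex,
  BMI, comorbidity, ASA, deprivation, pre-operative scores) matching the
  published cohort description;
* brand assignment through a provider layer: each synthetic hospital uses
  predominantly one brand (85% of its patients), and treatment-centre and
  consultant rates depend on the hospital's primary brand — so brand is
  confounded with provider, not with patient case mix, and
  confounding-by-provider adjustment is testable;
* post-operative EQ-5D-3L equal to a case-mix linear predictor plus
  Gaussian noise (residual SD 0.30), clamped to the instrument support
  [−0.594, 1]. Because clamping attenuates offsets, latent brand, sex and
  level parameters are obtained by inverting the clamped-normal mean at
  the total linear-predictor SD, so the *observed-scale* adjusted means
  match the configured targets (0.74 Nexgen vs 0.72 AGC Biomet for men
  aged 70, and so on) — the published tables print observed-scale values.
  The residual SD was calibrated by simulation so that brand-contrast
  standard errors at full cohort size are ≈ 0.003–0.004, the spread
  implied by the published probabilistic results;
* revision hazards that are two-piece within follow-up (an elevated
  year-1 early-failure rate, then constant), solved per brand and sex so
  the cumulative incidence at 5 and 10 years equals the published rates
  exactly at the reference profile; proportional case-mix effects on top;
  uniform accrual up to the brand-specific maximum observation period
  (11.1 years for PFC Sigma down to 6.7 for Triathlon; intermediate brands
  interpolated by market-introduction order);
* 17% missing post-operative outcomes, MCAR or MAR on observed age and
  pre-operative QOL.

What it does not emulate: dimension-level EQ-5D responses (only the
index), postcode-derived deprivation, database linkage error, exclusion
cascades (all records already satisfy the inclusion criteria), provider
random effects on outcomes beyond the two observed flags, and
non-proportional case-mix effects on revision. Passing tests therefore
show that the estimators recover the structure this generator encodes —
not that they would be unbiased under every real-data violation of it.

One structural honesty note: the truth's sex-specific hazards are not
exactly proportional between sexes (both printed rows are hit exactly),
while the analysis model treats sex as a proportional-hazards covariate,
as the source analysis did. The resulting approximation error at the
5- and 10-year anchors is about 1–2%, visible in the acceptance numbers.

## Numerical choices

* Clamped-mean inversion uses `uniroot` at tolerance 1e−12 on the closed
  form of a clamped normal mean.
* Two-piece rates from 5/10-year targets: `h2 = (H10 − H5)/5`,
  `h1 = H5 − 4 h2` on cumulative hazards; validation rejects targets with
  `p10 < p5` or ≥ 1.
* Spline fitting requires at least k + 2 distinct uncensored times; fitted
  cumulative hazards are checked for monotonicity on the observed range
  (warning if violated). Binary covariates whose events all fall in one
  level are dropped before fitting (the log hazard ratio would diverge);
  covariates without variation are dropped likewise.
* The Markov trace must conserve probability to 1e−12 per cycle; the dead
  state is absorbing.
* Ties in both cost and QALYs in the ICER ladder are broken by brand-name
  order, with a message.
* CSV output writes doubles with 17 significant digits so files round-trip
  exactly.

## Problem sizes

Default runs use the full study-scale cohorts (53 126 / 239 945 / 54 134
records, m = 20 imputations, 1 000 PSA draws); the complete
simulate–fit–evaluate pipeline for the two age-70 subgroups takes about
two minutes on one CPU. The test suite uses these sizes for the
end-to-end checks and smaller cohorts (thousands of records, m = 3–5) for
structural tests.

## Known limitations

* The QOL brand effects dominate the incremental results; with
  contrast standard errors of ≈ 0.004 (as the published spread implies), a
  single synthetic fixture determines the fitted contrast to only ±20%,
  and the incremental cost-effectiveness ratio inherits that spread across
  registry realizations.
* Extrapolating 45 years from ≤ 11 years of follow-up is an assumption of
  the restricted-spline tail (linear in log time); the piecewise scenario
  probes but cannot remove it.
* No provider-clustered (hierarchical) modelling: uncertainty in brand
  contrasts may be understated, a limitation the source analysis shares by
  design.
* Operative mortality is brand-constant and cancels from incremental
  results; its level (0.002) only shifts all brands equally.
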