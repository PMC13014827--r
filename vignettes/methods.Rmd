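---
title: "Methods: cost-utility analysis of benzodiazepine deprescribing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-utility analysis of benzodiazepine deprescribing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bzdcua)
```

## The evaluation problem

`bzdcua` evaluates, over a 6-month horizon and from the public-payer
perspective, whether supervised benzodiazepine (BZD) discontinuation in
primary care pays for itself: participants who taper off the drug might
need *more* follow-up visits and emergency contacts during withdrawal, or
*fewer* because adverse drug effects abate. The comparison is
observational — both groups receive the same deprescribing programme, and
"discontinuation" means no BZD dispensing during the final two months of
follow-up. Direct medical costs only (four visit categories); no
discounting (the horizon is half a year); pharmaceutical, diagnostic and
indirect costs deliberately excluded.

## Costing model

Per participant, cost is the inner product of four 6-month utilization
counts with tariff unit costs, summed without intermediate rounding.
Default tariffs (2024 euros): primary-care visit €64.07, hospital
specialist consultation €81.38, primary-care emergency visit €73.30,
hospital emergency visit €215.06. Historical tariffs are restated via CPI
index ratios (`inflate_cost()`); the packaged CPI series
(`cpi_synthetic.csv`) is a synthetic stand-in with plausible recent Spanish
annual index values — it exercises the mechanism and is irrelevant to the
default analysis, whose tariffs are already in 2024 euros.

Two rounding conventions coexist in the source material: summary tables
print integer euros while the CUA carries cents. The engine therefore
computes everything in full precision and rounds only at report rendering,
half away from zero (`round_half_up()`), which is what reproduces printed
cells such as 9.03 × 64.07 = 578.55 → 579. One tariff cell is printed
inconsistently at the source (73.30 in prose, 73.34 in the results table);
both tariff files ship (`tariffs_2024.csv`, `tariffs_2024_table2.csv`) and
the default follows the prose value. Group summaries expose unrounded
companion columns so either convention can be audited.

## Utilities and QALYs

The COOP/WONCA charts (7 items, each 1 best – 5 worst, total 7–35) are a
functional health-status instrument, not a preference-based one; no
validated tariff exists for it. Utilities are therefore derived by the
linear transform

\[ u = \frac{35 - \text{score}}{28} \in [0, 1], \]

an assumption inherited from the study design: monotone, group-symmetric,
and applied identically at both time points. Two QALY quantities follow
from a linear utility transition between baseline and month 6:

* absolute QALYs: \((u_0 + u_6)/2 \times 0.5\) (in \([0, 0.5]\));
* QALY gain: \((u_6 - u_0)/2 \times 0.5\) (in \([-0.25, 0.25]\)).

The source formula is the absolute one, but its published group values
(0.0275 / 0.0611) are numerically impossible under it: with baseline
utility ≈ 0.59, absolute half-year QALYs would be ≈ 0.3. Only the *gain*
reading reproduces those group means (Δu of 0.11 and 0.2444). The package
computes both and the CUA stage defaults to the gain; the discrepancy is
deliberately left auditable rather than silently resolved. Participants
missing the 6-month score are excluded from QALY analyses (complete-case);
imputation is out of scope.

## Cost-consequence comparison

Group means per category plus total cost, with Mann–Whitney rank tests.
The implementation uses midranks; the null distribution is enumerated
exactly over all \(\binom{n}{n_a}\) group assignments when the combined
sample is below 20 (the source is silent on the implementation; at n = 20
the normal approximation is already close, and enumeration is cheap below
it), and otherwise uses the normal approximation with tie-corrected
variance and continuity correction. Two-sided p doubles the smaller tail,
capped at 1; two all-identical samples give p = 1 by convention. The
difference column is oriented **discontinuation − continuation**
throughout the package (negative = saving), matching the published tables'
sign convention. No multiple-testing adjustment is applied (none was in
the source analysis).

## Utilization regressions

Per resource category, a log-link Poisson ML model of the count on group
and covariates; `IRR = exp(β)`, 95% Wald intervals, Wald p-values. No
exposure offset — every participant contributes the same 6-month window.
Reference levels are explicit configuration, never inferred from printed
tables (whose labelling of the group and comorbidity contrasts is
ambiguous): group = continuation, sex = women, income = ≤€18,000/year,
comorbidity band = CCI 0–2. The default predictor sets differ by outcome,
mirroring the published models: mental-disorder status enters the
primary-care and emergency models, sex the specialist and emergency
models.

A plain Poisson model does **not** "account for overdispersion" — its
variance is tied to its mean. The claim is left uncorrected in the fitted
default (to reproduce the source analysis) but `robust = TRUE` switches to
Huber–White sandwich standard errors, implemented directly
(bread = model-based covariance, meat = \(X^\top \mathrm{diag}((y-\mu)^2) X\)),
which is the standard remedy when counts are overdispersed. Degenerate
inputs are handled explicitly: rank-deficient designs error naming the
collinear columns; an all-zero outcome returns flagged records instead of
crashing; a factor level whose subgroup has all-zero counts triggers a
separation warning and a flag on the records.

## Deterministic CUA and dominance

With arm-level moments \((\bar C, SE_C, \bar E, SE_E)\) per group,
\(\Delta C\) and \(\Delta E\) are oriented discontinuation − continuation
and \(\mathrm{ICER} = \Delta C / \Delta E\), undefined (and flagged) when
\(\Delta E = 0\). Dominance: cheaper and more effective = dominant
(southeast); costlier and less effective = dominated; the two remaining
quadrants are trade-offs. Exactly-zero differences are assigned to the
more-effective / less-costly side — a measure-zero convention that keeps
quadrant accounting exact. The published ICER (−€2,185.71/QALY) was
evidently computed from unrounded means; dividing the printed rounded
differences gives −€2,184.52, and the package reports the full-precision
ratio of its actual inputs rather than forcing agreement with the printed
cent-level figure.

## Probabilistic sensitivity analysis

1000 Monte-Carlo iterations by default. Costs per arm are drawn from gamma
distributions with \(\alpha = \mu^2/\sigma^2\), \(\beta = \sigma^2/\mu\);
QALY gains per arm from beta distributions by method of moments
(\(\nu = \mu(1-\mu)/\sigma^2 - 1\), \(a = \mu\nu\), \(b = (1-\mu)\nu\)),
with the feasibility bound \(\sigma^2 < \mu(1-\mu)\) enforced before any
sampling. Three design choices deserve emphasis:

* **σ is the SE of the mean**, not the person-level SD. The source writes
  "σ² is the variance" without saying which; its tables report "(SE: …)",
  and parameter (second-order) uncertainty is what a PSA propagates. With
  the default inputs this yields an expected southeast share ≈ 0.83.
* **Independence everywhere**: arms, and costs versus QALYs within an arm,
  are sampled independently; no correlation structure is available to
  estimate.
* **Beta on the gain scale**: QALY gains can be negative in real cohorts,
  which a beta on \([0,1]\) cannot represent. Following the source, the
  beta is fitted to the (positive) published means; a negative mean raises
  an error instead of being silently rescaled.

Per-draw ICERs are reported (including histogram bins, the tabular
equivalent of the published figure), but the headline summary is the
quadrant decomposition: ratios are sign-ambiguous across quadrants.
Subgroup PSA re-estimates arm moments within strata (comorbidity band or
sex) and skips — with a warning and an explicit skip record — strata where
a group has fewer than two complete cases or moments are infeasible.

## The synthetic cohort: what it emulates, and what it does not

No participant-level data are deposited, so `generate_cohort()` simulates
the cohort structure the analysis assumes, calibrated to the published
marginals (packaged as `default_cohort_config.json`):

* **Group split**: Bernoulli with p = 107/330 ≈ 0.324, the complete-case
  split. (The source abstract says 45.6% of 333 discontinued — inconsistent
  with its own tables; the generator parameterizes the proportion rather
  than resolving this.)
* **Counts**: independent Poisson per category with group means 9.03/8.20,
  1.67/1.63, 0.58/0.31, 0.32/0.34. Independence across categories is a
  simplification (only group means are published); an optional lognormal
  common frailty (mean 1, `frailty_sdlog`) induces cross-category
  correlation and overdispersion for regression experiments.
* **Covariates**: independent draws from the published marginals, stored
  as exact count fractions (e.g. 233/333 women). The indication
  percentages sum to 93.4% as printed (missingness, presumably) and are
  renormalized; likewise comorbidity bands (printed counts sum to 330).
  Age ~ normal(66.72, 12.41) clipped to [18, 105] (SD back-computed from
  the printed SE 0.68 × √333); BZD duration ~ gamma moment-matched to
  (4.04, 5.11) years, floored at 0.1 (a normal would put a third of its
  mass below zero).
* **Quality of life**: baseline score ~ round(clip(normal(18.48, 5.11)))
  on the 7–35 scale (utility 0.59, SD from SE 0.01 × √333). The 6-month
  score is baseline − 28·Δu with Δu normal per group; change SDs are
  back-computed from the published QALY-gain SEs
  (SD(Δu) = 4·SE·√n: 0.520 continuation, 0.381 discontinuation).

**Truncation-aware calibration.** With change SDs that large, clipping to
[7, 35] censors many improvements (the floor at 7 is ≈ 2.2 utility-SDs
from the continuation-group 6-month mean), and the naive "draw and clip"
realized mean gain would undershoot the target by well over the advertised
tolerance. The generator therefore solves, per group and deterministically
given the seed, for the latent change location whose *post-clipping* mean
change equals the configured target (monotone root-finding on the cohort's
own draws). The configured mean is thus a realized-mean target, not a
latent parameter; `calibration_report()` tabulates configured versus
realized moments so this contract is visible.

Reproducibility: one root seed; each variable block (covariates,
assignment, counts, scores) consumes an independently derived sub-stream,
so adding or reordering blocks does not perturb the others. Identical
config + seed gives byte-identical CSV output.

What the generator does **not** emulate — so a green calibration test does
not establish it: cross-category and cost–outcome correlations, covariate
effects on utilization (covariates are independent of counts by default,
so synthetic regression IRRs for age, income etc. are null), informative
missingness (no missing data are generated), overdispersion beyond Poisson
(unless frailty is enabled), and any dependence of discontinuation success
on baseline characteristics (optional logistic assignment exists for
confounding experiments but is off by default). Synthetic arm-level cost
SEs are Poisson-driven and smaller than the published ones, which embed
real-world overdispersion; PSA acceptance checks therefore use the
published moments directly.

## Numerical conventions collected

* Integer-euro rendering rounds half away from zero; computation is never
  rounded.
* Mann–Whitney: exact below combined n = 20; doubling-the-smaller-tail,
  capped at 1; all-identical data give p = 1.
* Quadrant accounting is exact: the four proportions sum to 1 with
  boundary draws assigned deterministically.
* Beta/gamma moment feasibility is checked before sampling; violations
  error with the bound stated.
* The group-size warning (an empty group at an extreme seed) is a warning
  at generation and a hard error at any between-group comparison.

## Limitations

The utility transform is unvalidated by construction (no COOP/WONCA
tariff exists); results should be read as comparative, not absolute. The
6-month horizon cannot capture relapse or long-term harms. The synthetic
cohort reproduces margins, not joint structure, so it validates the
pipeline's arithmetic and statistical procedures rather than the clinical
findings. Poisson CI coverage and calibration checks are Monte-Carlo
statements at fixed seeds: individual cells can fluctuate outside tight
bands (a ~1.4% relative SE cell against a 2% band fails for a substantial
minority of seeds) without indicating bias.
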