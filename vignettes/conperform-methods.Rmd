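---
title: "Deriving a continuous pulmonary-embolism risk score by AUC maximization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a continuous pulmonary-embolism risk score by AUC maximization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conperform)
```

## The problem and the model

Early risk stratification in acute pulmonary embolism (PE) guides whether a
patient can be discharged early or needs intensive monitoring. Established
discrete scores bin continuous physiology into point categories, which makes
the score discontinuous exactly where decisions are hardest: near bin
edges, clinically indistinguishable patients can receive very different
totals. `conperform` implements a continuous alternative built from three
objective parameters available at presentation — age (years), heart rate
(bpm), and arterial oxygen partial pressure PaO2 (mmHg):

$$G = k_{age} \cdot Age + k_{hr} \cdot HR - k_{PaO_2} \cdot PaO_2 .$$

PaO2 enters negated because lower oxygenation means higher risk. The score
is used ordinally: only the ranking of patients matters, and whether a raw
$G$ value is negative has no clinical meaning. Covariates are deliberately
left on raw clinical units — the score a clinician computes by hand is the
score the model analyzes.

Weights are chosen to maximize the area under the ROC curve (written $Q$
throughout) of $G$ against 30-day all-cause mortality. Because multiplying
all three weights by a positive constant is a strictly increasing transform
of every patient's score, the ROC curve and $Q$ are scale-invariant; the
weight triple is therefore identified only up to direction and is
normalized to the simplex $k_{age} + k_{hr} + k_{PaO_2} = 1$, then
reparameterized to two free coordinates on the unit square:
$x = k_{age}$ and $y = k_{hr} / (k_{hr} + k_{PaO_2})$, with
$k_{hr} = (1-x)y$ and $k_{PaO_2} = (1-x)(1-y)$. `expand_weights()` and
`reduce_weights()` implement the two directions of this map; the package
asserts in its tests that they are mutually inverse and that the expansion
always lands on the simplex.

## The optimization procedure

$Q(x, y)$ is a piecewise-constant function of the weights (it changes only
when two patients swap rank), so gradient methods are unsuitable. The
derivation instead smooths the surface with a polynomial surrogate:

1. `sample_weight_pairs(n, seed)` draws $n$ candidate pairs i.i.d. uniform
   on $(0,1)^2$; the default design is $n = 5000$.
2. `evaluate_surface()` expands each pair, scores every patient, and
   computes $Q$ as the tie-corrected Mann–Whitney rank statistic
   (identical to the trapezoidal area under the tie-collapsed empirical
   ROC curve; the identity is exercised exhaustively in the tests).
3. `fit_polynomial_surface()` fits $\tilde Q(x,y)$ by ordinary least
   squares on the complete monomial basis $x^i y^j$, $i + j \le d$
   ($(d+1)(d+2)/2$ terms; 36 at the default $d = 7$). Monomials are
   evaluated at raw $(x, y)$ — the surrogate is reported in raw powers —
   and design columns are rescaled to unit root-mean-square before the QR
   solve purely for conditioning.
4. `maximize_surface()` takes the global maximum over the *closed* unit
   square: a dense interior grid scan (501 × 501 by default) followed by
   bounded local polish (`optim`, L-BFGS-B) from the ten best grid points,
   compared against 1-D maximizations along each boundary edge. On random
   low-degree polynomials the result agrees with a 2001 × 2001 brute-force
   grid to better than $10^{-4}$ in value (a frozen oracle test).
5. `optimize_weights()` chains the stages, expands the argmax to the weight
   triple, and recomputes the AUC *directly* at those weights
   (`q_true`).

Two quantities could be called "the" maximum AUC: the surrogate value at
its argmax and the direct AUC at the corresponding weights. The package
treats the direct AUC as authoritative in every report and keeps the
surrogate value as a diagnostic, together with their relative difference
(`relative_error`); on smooth synthetic surfaces this difference stays
below 0.1%, and the acceptance suite asserts exactly that.

Two diagnostics mirror how such a derivation is audited. The in-sample
$R^2$ of nested fits is non-decreasing in the order by construction;
`order_selection_table()` tabulates it for orders 1–8 so the plateau (and
hence the sufficient order — 7 by default) is visible. Whether in-sample or
held-out $R^2$ is the right yardstick is genuinely open; in-sample is
implemented because the surrogate's only job is interpolation over the
sampled design, not out-of-sample prediction. `stability_analysis()`
repeats the whole chain for several design sizes (1000–6000 by default,
independent seeds) and reports the relative fluctuation of the surrogate
maximum, which on well-behaved cohorts sits well below 0.1%.

## ROC machinery and thresholds

`roc_curve()` emits one vertex per distinct score value (ties collapse) and
the terminal points; `auc()` is the rank statistic described above, exactly
equal to pair counting with ties worth 1/2. The "optimal" cutoff is the
observed score maximizing Youden's $J$ = sensitivity + specificity − 1
under the rule *event when score ≥ threshold*; no selection criterion is
universal, and Youden's $J$ is adopted as the standard one for this
reporting style. Ties in $J$ (detected with a $10^{-12}$ tolerance, far
below the $1/(n_+ n_-)$ spacing of attainable $J$ values) are broken
toward higher specificity, then the lower threshold. Confidence intervals
for the AUC use a stratified percentile bootstrap (2000 replicates by
default, seeded); the bootstrap was chosen because it makes no variance
approximation and is reproducible under a seed. Analytic (DeLong-type)
variances are deliberately out of scope.

Published analyses of this score family report slightly different cutoffs
on overlapping data (55.6 and 56.2 appear for the same cohort), and the
selection rule behind them is not recoverable. `stratify_cohort()`
therefore always takes the threshold as an explicit argument — with the
documented convention *high risk ⇔ score ≥ threshold* — and never
hard-codes either value.

## Stratified outcome tabulation

`outcome_distribution()` tabulates the three exhaustive clinical states —
still hospitalized, discharged, dead — at evaluation days (10, 20, 30 by
default). The model is deliberately minimal: each patient is hospitalized
until at most one absorbing event (death or physician-approved discharge)
within the 30-day window; patients with no recorded event remain
"hospitalized" at every day. Proportions therefore sum to 1 at each day,
death and discharge curves are non-decreasing, and no censoring machinery
(Kaplan–Meier, competing risks) is involved — raw state proportions are
what this analysis style reports.

## The synthetic cohort generator

No patient-level data ships with the package; `generate_cohort()` produces
seeded cohorts that emulate the derivation study's structure at any size:

* **Covariates.** Truncated normal marginals: age mean 75 SD 14 years on
  [18, 105]; heart rate mean 85 SD 19 bpm on [40, 180] — the published
  summary moments of the derivation cohort (read as mean (SD); the table
  does not say so explicitly, which is assumed and documented here).
  No PaO2 summary is published, so the default is mean 75 SD 15 mmHg on
  [30, 110], chosen to span all four discrete scoring bins; it is fully
  configurable. Uncorrelated draws use the exact inverse-CDF method;
  a user-supplied correlation matrix switches to joint-normal sampling
  with rejection of out-of-bounds rows (truncation then attenuates the
  realized correlation slightly, which the tests account for).
* **Outcome.** $\mathrm{logit}\,P(\text{death}) = b_0 + s\,(w_{age} Age +
  w_{hr} HR - w_{PaO_2} PaO_2)$ with the weight direction normalized to the
  simplex. The logistic link makes the configured direction the
  Bayes-optimal linear discriminant, which is exactly what the optimizer's
  parameter-recovery tests need. The intercept $b_0$ is root-found
  (`uniroot`) on the cohort's own covariate draw so the mean event
  probability hits the target rate — default 43/559 ≈ 7.7%, the derivation
  study's mortality. The effect scale defaults to $s = 0.15$ logits per
  score unit, putting the linear-predictor SD near 1.5 and the AUC of the
  true direction in the low 0.8s, the regime the method was reported in.
* **Event days.** Deaths draw a day from a truncated geometric
  (rate 0.15) on 1–30, weighting deaths early as clinically expected;
  survivors draw a discharge day from round(Normal(15, 7)) clipped below
  at 1, with draws past day 30 left as "still hospitalized" (a few percent
  of survivors). These shapes reproduce the qualitative trajectory pattern
  of the published risk groups (most low-risk patients discharged by day
  20, a small hospitalized remainder at day 30) without claiming their
  exact percentages.

What passing tests on these cohorts shows — and does not show. The
generator's outcome model is exactly the linear-logistic mechanism the
optimizer assumes, covariates are (truncated) Gaussian, and there is no
measurement error, missingness beyond what tests inject, or cohort drift.
Parameter recovery and calibration results on synthetic cohorts therefore
validate the *machinery*, not clinical performance; cohort-specific
published figures (AUCs near 0.84/0.77, thresholds near 56) depend on the
clinical data and are not reproduced, only their qualitative pattern is.

## Numerical choices and degenerate inputs

* Problem sizes in the test suite are chosen to keep the full run in a few
  minutes: recovery cohorts of $n = 2000$ with the full 5000-point design,
  diagnostics on $n = 559$, unit tests on desk-scale fixtures. Recovery is
  asserted within 0.1 per weight component at $n = 2000$, the point where
  sampling noise no longer dominates.
* The optimizer's argmax is clamped into the open square by $10^{-9}$
  before expansion (the simplex map is defined on the open square); a
  boundary argmax is reported via `location = "boundary"`.
* Single-class cohorts, empty tables, non-finite covariates, under-
  determined fits (fewer points than basis terms) and non-bracketing
  intercept calibrations all fail fast with named errors rather than
  propagating NaNs; records with both a death day and a discharge day are
  data errors.
* Cohort splitting assigns `round(ratio × n)` records to training (559 at
  2:1 gives 373/186). The published randomization is not described as
  outcome-stratified, so simple randomization is the default and a
  stratified option is provided.
* All randomness flows through explicit integer seeds (`withr::with_seed`),
  so cohorts, bootstrap intervals, designs and whole CLI runs are
  bit-reproducible; stability analyses derive per-size seeds by offsetting
  the master seed.

## Known limitations

The score family is linear with constant weights; patient-level
heterogeneity, additional covariates, imputation of missing vitals, and
sensitivity-optimized variants are out of scope, as are the external
severity indices sometimes used as comparators (their formulas are not part
of this package's sources). The surrogate approach assumes the AUC surface
is smooth enough for a degree-7 polynomial after Monte-Carlo averaging;
`relative_error` and `stability_analysis()` are the built-in ways to check
that assumption on any new cohort.
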