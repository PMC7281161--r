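---
title: "From SRM peak-area ratios to a prognostic protein panel: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From SRM peak-area ratios to a prognostic protein panel: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srmpanel)
library(dplyr)
```

srmpanel implements a complete analysis route for targeted-proteomics
prognosis studies: isotope-dilution quantification of selected-reaction-
monitoring (SRM) measurements, single-marker evaluation against binary and
survival endpoints, and construction of a multi-protein logistic
classifier with a constrained, bootstrapped decision threshold. This
vignette explains the models behind each stage, the tunable parameters and
their defaults, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## 1. Quantification model

### Calibration

Stable-isotope-labelled ("heavy") peptide standards are spiked into a
pooled digest at a ladder of known concentrations (default levels 0, 0.6,
3, 12, 60, 300, 1500, 3000, 6000, 12,000, 24,000 and 48,000 amol/µg, three
injection replicates each). Because the endogenous ("light") peptide
content of the pool is constant, the heavy-over-light peak-area ratio is
linear in the spike concentration:

$$ \mathrm{H/L} = \beta_1 \, X + \beta_0 , $$

where $X$ is the heavy concentration (amol/µg). `fit_response_curve()`
estimates $\beta_1$ (slope) and $\beta_0$ (intercept) by ordinary least
squares over **all replicate points** rather than level means. With a
balanced design the two are identical in expectation and coincide exactly
in the noiseless case; using replicates keeps the replicate-level
information in the fit diagnostics.

### Detection and quantification limits

For each level the signal-to-noise ratio is the peak apex intensity over
the highest background in a retention-time window around the peak
(`compute_snr()`; a zero background with signal present yields an infinite
S/N sentinel). The LOD is the lowest level whose replicate S/N reaches 3;
the LOQ additionally requires S/N ≥ 10 and a replicate coefficient of
variation of the H/L ratio below 20 % (CV = sd/mean). Replicate S/N values
are summarised by the **median**, a choice this package makes (the rule's
usual statement is silent on the summary; the median is robust to a single
aberrant injection). A level with fewer than two replicates has no defined
CV and cannot qualify as LOQ. When no level qualifies the limit is an `NA`
sentinel rather than an error — undetectable assays are a real outcome,
e.g. when heavy-transition interference swamps the signal.

### Matrix light concentration and back-calculation

Inverting the calibration line at a spike level $X$ gives an estimate of
the pool's light content: $\hat c_\mathrm{light} = X / (\mathrm{H/L} -
\beta_0)$. `estimate_matrix_light_conc()` averages this over the three
mid-curve levels (300, 1500, 3000 amol/µg), using the **measured** (not
curve-predicted) mean ratio at each level; measured ratios preserve the
exact-recovery property under the ideal model, and the mid-curve levels
sit comfortably above the LOQ while staying in the linear range. Levels
whose intercept-corrected ratio is non-positive are excluded; if all are,
that is an error.

Study samples receive a single heavy spike $c_\mathrm{heavy}$ (default
300 amol/µg) and yield a light-over-heavy ratio. The endogenous
concentration is

$$ c_\mathrm{endo} \;=\; \frac{\dfrac{\mathrm{L/H} \; c_\mathrm{heavy}}
{c_\mathrm{light}} - \beta_0}{\beta_1} . $$

The fraction's ordering is a deliberate design decision: the product
$\mathrm{L/H} \times c_\mathrm{heavy}$ estimates the endogenous
concentration directly under equal heavy/light response, and dividing by
$c_\mathrm{light}$ converts it onto the calibration curve's response axis
(where the curve measured heavy against the pool's light content).
Concretely, under the ideal model $\beta_0 = 0$, $\beta_1 =
1/c_\mathrm{light}$, the formula reduces to $\mathrm{L/H} \times
c_\mathrm{heavy}$ — the textbook isotope-dilution estimate — and the
forward model round-trips to machine precision, which the test suite
verifies over randomised curve parameters. The alternative ordering (with
$c_\mathrm{light}$ and $c_\mathrm{heavy}$ exchanged) does not recover
truth under any consistent forward model and is not offered.

Negative back-calculations (possible when $\mathrm{H/L}$ noise pushes the
corrected ratio below zero) are clamped to 0 and flagged
`negative_clamped`. Values below the LOD/LOQ keep their numeric estimate
and are only flagged (`below_lod`, `below_loq`): downstream stages see the
full numeric vector by default, and any censoring policy (e.g. LOD/2
imputation) is the caller's explicit choice. This keeps rank-based
statistics unaffected while making detection status auditable.

`quantify_samples()` rolls peptides up to proteins with one designated
surrogate peptide per protein (the assay configuration this pipeline
models measures 16 proteins by 16 peptides); a mean-of-peptides roll-up is
available behind `rollup = "mean"` but is not default, since peptides of
one protein can differ in recovery and a fixed surrogate is the more
reproducible convention.

## 2. Marker evaluation

Markers are analysed on a standardized log10 scale
(`transform_log10z()`): concentrations span orders of magnitude and are
right-skewed, and reported cut-points for such panels are small signed
numbers consistent with z-scores of logs, not raw amol/µg. The transform
is a configurable pipeline stage (`transform = "none"` accepts
pre-transformed input). Zeros are offset by half the smallest positive
value per marker before the log.

* **AUC** (`marker_auc()`): tie-corrected Mann–Whitney statistic divided
  by $n_+ n_-$, with a class-stratified percentile bootstrap CI (default
  B = 1000) and a normal-approximation Mann–Whitney p-value for
  AUC = 0.5. Stratified resampling guarantees both classes in every
  replicate, which matters at the event counts typical here (tens of
  events). The per-marker p-value is a package choice; reference analyses
  of this design do not state their test, and their printed p-values are
  not monotone in AUC, so no attempt is made to chase them.
* **Constrained cut-point** (`constrained_cutpoint()`): candidate
  thresholds are midpoints between consecutive sorted unique values plus
  $\pm\infty$, which exhausts every achievable 2×2 table. Among candidates
  meeting the NPV and specificity floors, the one with maximal sensitivity
  wins; ties break to higher specificity, then to the larger threshold
  (the more conservative rule: fewer predicted positives). Constraints are
  evaluated as "at least" (≥) by default with a `strict` switch, since the
  constraint sets are stated both ways in the literature this models. An
  undefined NPV (no predicted negatives) never satisfies a positive floor.
  Markers protective at high values (AUC < 0.5) are flipped before the
  search and the cut-point mapped back, with the orientation recorded.
  The default floors are NPV 0.80 / specificity 0.40 for the metastasis
  endpoint and 0.70 / 0.30 for biochemical recurrence.
* **Panel screen** (`pca_panel_screen()`): eigendecomposition of the
  marker correlation matrix with the Kaiser eigenvalue-greater-than-1
  retention rule.
* **Survival**: Kaplan–Meier estimation, log-rank tests and Cox models
  delegate to the survival package; the package's own tests check them
  against hand product-limit and observed-minus-expected computations.
* **Cohort description** (`summarize_cohort()`): ANOVA and Kruskal–Wallis
  in parallel for continuous variables; Pearson chi-square **without**
  continuity correction for categorical ones, switching to Fisher's exact
  test when any expected cell is below 5. The no-correction choice is
  validated against a published three-group race contingency table whose
  p-value (0.5882) reproduces exactly.

## 3. The panel classifier

The classifier cohort is the metastasis-vs-nonevent subset. It is split
70/30 by a **simple** random split with `floor(0.7 n)` training patients —
not stratified, because the reference design's printed event fractions
differ between training and testing sets, which a stratified split cannot
produce. Univariable logistic regression selects markers with Wald
p < 0.05 **and** AUC > 0.65 (both strict). The AUC gate is applied on the
oriented scale `max(a, 1 - a)`: protective markers (lower values in
events) are as informative as risk markers, the field reports their AUC
oriented, and the logistic coefficient's sign carries the direction into
the panel fit; `orient = FALSE` restores the raw-scale gate. The multivariable logistic fit
of the selected panel gives the score

$$ s(x) = 100 \cdot \operatorname{logit}^{-1}(\hat\beta_0 +
\hat\beta^\top x) \in [0, 100], $$

i.e. "scaled from 0 to 100" is implemented as predicted probability × 100.
This is naturally bounded, monotone in the linear predictor, and puts a
decision threshold of single-digit magnitude on a cohort with a minority
event class — consistent with the reported behaviour of such classifiers.
A min–max rescaling of the linear predictor was considered and rejected:
it depends on the realised sample extremes and is not comparable across
cohorts.

Perfect separation or collinearity in any logistic fit (common in
bootstrap replicates of small cohorts) triggers a small ridge-penalised
Newton fit (penalty 1e-3 on non-intercept coefficients) instead of
failure, flagged on the returned model.

The decision threshold maximises sensitivity subject to NPV ≥ 0.90 and
specificity ≥ 0.35 on the training scores, using the same constrained
search as the single-marker cut-points. Its confidence interval is the
percentile interval of per-replicate optimal thresholds over 1000
bootstrap resamples. By default each replicate **re-fits** the logistic
model on the resampled training set before re-thresholding
(`train_classifier(refit = TRUE)`), so the interval reflects model-fitting
variability; `refit = FALSE` re-thresholds fixed scores only. Added value
over standard-of-care covariates is tested by likelihood-ratio comparison
of nested logistic models, and the classifier's prognostic effect by Cox
models over two covariate sets — biopsy (age, race, clinical risk
stratum) and pathology (pathological T, top grade group vs the rest,
surgical margins) — with the classifier either dichotomised at the
threshold or continuous. The proportional-hazards assumption is checked
per covariate by the scaled-Schoenfeld-residual trend test at α = 0.05
and reported, not enforced; the trend test is this package's choice of
check.

## 4. The synthetic-data generator

`simulate_cohort()` produces cohorts with the statistical structure the
analysis assumes, so every stage is testable without restricted patient
data:

* outcome classes drawn at the study prevalences (nonevent / recurrence /
  metastasis ≈ 0.476 / 0.367 / 0.157 of n = 338);
* marker values as equal-variance binormal standardized log-abundances,
  $N(\mu_g, 1)$, with group shifts $d = \sqrt2\,\Phi^{-1}(\mathrm{AUC})$
  planted from the published per-marker discriminations — the binormal
  model makes target AUCs analytically controllable, which is the only
  quantitative handle available. Tissue PSA's shift is negative for
  metastasis (lower levels in progressors);
* clinical covariates drawn from the published per-group marginal
  frequencies (a categorical lookup, not a causal model);
* exponential event times parameterised by median (20.4 months to
  recurrence, 80.4 to metastasis), with nonevents censored uniformly in
  [120, 253] months, matching the at-least-ten-years nonevent definition;
* `simulate_calibration()` and `simulate_srm_from_cohort()` push true
  concentrations through the linear response model with multiplicative
  log-normal noise (median-unbiased; default CV 10 %). The generated S/N
  rises linearly through a planted LOD so the limit rules are exercised,
  and true concentrations map from latent z-scores as
  $c = c_\mathrm{light} 10^{0.3 z}$.

What the generator does **not** emulate: inter-marker correlation (no
published estimates exist; markers are independent given the outcome
group), batch and run-order effects, non-linear response at the extremes
of the ladder, heteroscedastic noise, and any causal dependence of
markers on clinical covariates beyond the shared outcome group. The
grade-group endpoint's marker discrimination arises only indirectly
(through the group-dependent covariate lookup), so passing tests speak to
the metastasis and recurrence endpoints, not to grade discrimination on
real data. More generally, green tests show the machinery is correct
under the stated model, not that real cohorts satisfy the model.

## 5. Numerical choices and degenerate inputs

* Cut-point candidates include $\pm\infty$, so "classify everyone" rules
  compete on equal footing; NPV/PPV with empty denominators are `NA` and
  fail positive constraints.
* Bootstrap draws are stratified by class and driven by explicit seeds
  (`withr::with_seed`), leaving the caller's RNG stream untouched; all
  stochastic outputs are bit-reproducible for a fixed seed.
* A calibration with a single distinct level is a singular-fit error;
  with two levels the fit proceeds under a warning.
* Grade-group dichotomisation defaults to groups 3–5 vs 1–2 for the
  grade endpoint (`gg_high = 3:5`, configurable to `4:5`, the other
  convention in use), and to group 5 vs 1–4 inside the pathology Cox
  model.
* Likelihood-ratio tests verify nesting via term subsets and equal
  observation counts; a zero-df comparison returns p = 1.

## 6. Problem sizes in the shipped checks

The package's tests and the acceptance script run everything at desk
scale: oracle equivalences on ≥ 1000 randomised instances of n ≤ 50;
planted-AUC recovery at n = 5000 (tolerance ±0.02, the binomial standard
error at that size); logistic and Cox recovery over 200 simulations of
n = 500 and n = 300; and 50 end-to-end training runs at the study's
cohort size, each of which must emit a threshold satisfying its
constraints on training data. These sizes were chosen so that sampling
noise sits well inside the asserted tolerances.

## 7. Known limitations

* The per-marker p-value is a Mann–Whitney approximation, not the
  unstated test behind the reference analyses; single-marker p-values
  should be compared across markers within this package only.
* Below-detection handling is flag-and-keep; sensitivity of downstream
  results to censoring policy is the user's analysis.
* The ridge fallback's penalty (1e-3) is fixed, not tuned; it exists to
  keep bootstrap replicates finite, not to regularise the headline fit.
* The generator's independence assumptions make panel AUCs optimistic
  relative to correlated real markers; treat simulated panel performance
  as an upper bound.
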