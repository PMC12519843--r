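---
title: "Compatible aboveground-biomass models from LiDAR tree metrics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compatible aboveground-biomass models from LiDAR tree metrics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fircompat)
```

## The modelling problem

Aboveground biomass (AGB) of a tree is the sum of four components — trunk
(stem wood), bark, branch, and leaf mass. Allometric models predict each of
these from size covariates; here the covariates are LiDAR-derived tree
height `lh` (m) and crown diameter `lcd` (m), which makes the models usable
wherever individual trees can be segmented from UAV point clouds without
felling or field mensuration. The package implements the three model layers
used in compatible-biomass work on Chinese fir (*Cunninghamia lanceolata*)
plantations, each adding structure to the previous one:

1. **Base forms** (`fit_base()`): four candidate mean functions per
   component — logistic `a/(1 + b e^{-c·lh - d·lcd})`, linear
   `a·lh + b·lcd - c`, exponential `a·e^{-b·lh - c·lcd}`, and power
   `a·lh^b·lcd^c` — compared by AIC with a parsimony tie-break
   (`rank_models()`): if the top two forms are within 2 AIC units, the one
   with fewer parameters wins. In the published study this rule is what
   selects the 3-parameter power form over the 4-parameter logistic.
   The sign conventions are kept exactly as published (the exponential form
   carries negative signs inside, so its fitted `b`, `c` come out negative).

2. **Age-group dummy models** (`fit_dummy()`): stands are classed into five
   development stages (1 young, 1–10 y; 2 middle-aged, 11–20 y; 3
   near-mature, 21–25 y; 4 mature, 26–35 y; 5 over-mature, >36 y). The
   power model gains one scale coefficient per group,
   `(Σ b0i·AGi)·lh^b·lcd^c`, with the exponents shared across groups. All
   five scales are estimated directly — no reference category is dropped,
   because the multiplicative form has no separate intercept; the usual
   "n − 1 dummies" rule applies only to additive encodings. The base power
   model is the equal-scales special case, so the dummy model's training
   RSS can never exceed the base model's (a nesting property the test suite
   checks on every dataset).

3. **The additive NSUR system** (`fit_nsur()`): component equations fitted
   independently predict a component sum that differs from a directly
   fitted total — the compatibility problem. The system estimator fits the
   four component equations *jointly* and defines the total as their exact
   sum. The total is never a fifth fitted equation: it is an identity, and
   estimating it alongside the components would make the residual
   covariance singular. Predictions from `predict()` on an `nsur_fit` are
   therefore additive for every input, bit for bit.

## The NSUR estimator

`fit_nsur()` implements iterated feasible generalized least squares
(IFGLS). With residual matrix `R` (n trees × 4 equations):

1. start from equationwise dummy-model fits (supplied or computed);
2. estimate `Σ̂ = R'R/n` (the 1/n divisor, not 1/(n−p); simple,
   deterministic, and immaterial at these sample sizes);
3. minimise the stacked GLS criterion `Σ_i r_i' Σ̂⁻¹ r_i` by
   Levenberg–Marquardt on residuals whitened with the Cholesky factor of
   `Σ̂⁻¹`, using the analytic block-diagonal Jacobian;
4. re-estimate `Σ̂` and repeat until the maximum relative parameter change
   is below `outer_tol` (default 1e-8, at most 100 outer iterations).
   Convergence is declared on the parameters; `Σ̂` at the final iterate is
   reported.

A singular `Σ̂` (e.g. duplicated residual streams) is ridge-regularised by
adding 1e-8 of the mean diagonal, with a warning. Parameter covariance is
the GLS expression `(J'(Σ̂⁻¹ ⊗ I)J)⁻¹` evaluated by SVD, so
non-identifiability surfaces as huge or infinite standard errors rather
than a failure.

`sigma_structure = "diagonal"` restricts `Σ̂` to its diagonal. This makes
the GLS criterion separable across equations, so the system estimates
coincide with equationwise NLS — the uncorrelated-error limit. It exists
because the *sample* covariance of uncorrelated errors is never exactly
diagonal at finite n: with the unrestricted `Σ̂` the joint estimates
legitimately differ from equationwise NLS by the order of the sample
cross-correlations (about 1e-2 at n = 300), and the restricted structure is
the clean way to express, and test, the diagonal-limit equivalence.

**Efficiency.** Textbook SUR gains efficiency over equationwise LS when the
error terms correlate *and* the regressor sets differ across equations.
Here every equation uses the same covariate pair and the same age-group
indicator structure; only the fitted exponents differ. In that
near-identical-regressor design the GLS gain is essentially nil — our
Monte-Carlo comparison (50 replicates, pairwise error correlation 0.7)
shows sampling-variance ratios within a few percent of 1 in both
directions. The value of the system estimator in this setting is therefore
*compatibility* (exact additivity) and the cross-equation residual
covariance it reports, not variance reduction; the test suite pins
efficiency parity rather than a superiority that this design cannot
produce.

## Fitting machinery and numerical choices

All nonlinear fits run Levenberg–Marquardt (`minpack.lm::nls.lm`) with
analytic Jacobians; tolerances are `ftol = 1e-12`, `ptol = 1e-10`, at most
200 iterations, and the accepted-iteration RSS trace is stored (it is
non-increasing by construction, which the suite verifies). Starting values
are deterministic:

* power: OLS on `log y ~ log lh + log lcd`;
* exponential: OLS on `log y ~ lh + lcd`;
* linear: the OLS solution itself;
* logistic: `a ← 1.05·max(y)`, then OLS on the logit linearisation
  `log(a/y − 1) ~ lh + lcd` for `b`, `c`, `d`;
* dummy model: the base power fit with every group scale started at its
  `a`; NSUR: the dummy fits.

Standard errors come from `σ̂²(J'J)⁻¹` via SVD of the Jacobian. These are
the conventional unweighted NLS errors and assume homoscedastic residuals.
Because real biomass residuals (and the generator's error model) have
dispersion roughly proportional to the mean, the package also provides
power-of-the-mean variance weighting (`variance_power = λ`, residuals
weighted by `1/mean^λ` in a second IRLS stage; `λ = 1` matches a
constant-CV multiplicative error). Unweighted fitting remains the default
— the convention of the published tables — but the coverage checks in the
test suite pair the weighting with the generator's error model, since
unweighted standard errors are mis-scaled under it (we measured ~74% joint
3-SE coverage unweighted versus ~95% or more with `λ = 1`).

`aic_ls()`/`bic_ls()` use the Gaussian likelihood concentrated over the
error variance, `ln L = −(n/2)(ln(2π·RSS/n) + 1)`, the standard surrogate
for least squares. Two conventions are pinned deliberately because they
differ from common defaults: `rmse()` uses the **n − 1** denominator, and
`tre()` is the **absolute-deviation** total relative error
`Σ|y−ŷ|/Σy` (a signed variant is available via `signed = TRUE`).

## The synthetic stand generator

The tree-level data behind the published coefficient tables are not
distributable, so `generate_stand()` produces stands with the statistical
structure the analysis assumes, letting every downstream stage be exercised
end to end. Its defaults were fixed once, from the published summary
tables, and are not tuned to test outcomes:

* **Truth parameters**: the published compatible-system coefficients (the
  only fully specified per-age-group parameter set available),
  `published_sur_system()`.
* **Covariates**: per-group `lh` from a truncated lognormal
  (`sdlog = 0.18`, envelope 2.7–31.7 m — the published min/max range) with
  group means (8.0, 11.0, 13.5, 16.0, 17.5) m. The published table reports
  only pooled moments (mean ≈ 13.1 m); the per-group means are interpolated
  to increase with stand age, which also reproduces the published pattern
  of group-mean biomass rising from young to mature stands.
  `lcd = 0.23·lh^0.9` times lognormal noise (`sdlog = 0.4`), giving the
  pooled crown-diameter mean ≈ 2.3 m with the right skew crown metrics
  show.
* **Errors**: mean-one multiplicative lognormal per component
  (`cv = 0.10`) with a Gaussian copula across components (pairwise 0.5 by
  default) — SUR is only distinguishable from equationwise NLS when errors
  correlate.
* **Additivity**: the total is always computed as the exact component sum;
  it is never drawn.
* **Determinism**: one integer seed; the draw order (per group: height
  uniforms, crown-noise normals, the n×4 error-copula normals) is part of
  the reproducibility contract, and identical configs produce byte-identical
  CSVs.

`generate_from_allocation()` covers the second data path: DBH/height drawn
from a joint lognormal, total biomass from `M_A = a0·D^{a1}·H^{a2}`,
components by the ratio split `(1, g1, g2, g3)/(1+g1+g2+g3)` — conservation
is enforced bit-exactly with a one-ulp fix-up on the residual component —
and `lh`/`lcd` attached as noisy proxies. The national standard's
species-specific coefficients are not printed in the source study and are
**not** shipped; `placeholder_allocation_params()` is clearly synthetic and
exists for tests and examples only.

What the generator does **not** emulate: spatial structure (no tree
placement, crown overlap, or segmentation errors), covariate measurement
error in `lh`/`lcd` for the main path, plot-level random effects, and any
age-group covariate overlap pathology. Passing tests therefore demonstrate
correctness of the estimators under the assumed error structure, not
field-data performance.

## Published reference tables

`published_table()` ships the study's summary and coefficient tables
verbatim. Three caveats are encoded rather than corrected:

* The biomass-summary table contains internally inconsistent printed rows
  (e.g. a trunk mean duplicating the bark mean in two places, a branch mean
  duplicating the leaf mean, one minimum equal to its mean). These carry
  `typo_flag`s, and only the six internally additive rows participate in
  the additivity checks.
* The system-definition equation block and the results prose disagree on
  whether `Msg` is trunk or bark; the package follows the system-definition
  convention (trunk) everywhere and keeps printed values verbatim.
* The base-model table's bark and trunk RMSE magnitudes (≈14 vs ≈2.2 kg)
  are inconsistent with bark being the far smaller pool, consistent with
  the same label swap; values are stored under their printed labels.

A checksum test guards the shipped tables against accidental edits.

## Problem sizes used by the test suite

Suite sizes are the package's own choice, balancing statistical power
against runtime: noise-free recovery uses 150–300 trees; the diagonal-limit
oracle 300 trees per seed; coverage checks 50 replicates at n = 2000
(base), 2500 (dummy, 500/group) and 2000 (NSUR, 400/group); the efficiency
comparison 50 replicates at 500 trees. The full suite runs in well under a
minute on one core.

## Limitations

* Age enters only as the five-class factor; no continuous-age or
  mixed-effects extension.
* No error-in-variables treatment of the LiDAR covariates; the implemented
  estimator is SUR.
* The split is a single stratified 7:3 partition; no cross-validation
  machinery.
* Units are fixed (m, kg) by design — unit conversion is error surface
  without benefit here.
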