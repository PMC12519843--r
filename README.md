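# fircompat

Compatible aboveground-biomass modelling for Chinese fir (*Cunninghamia
lanceolata*) plantations from LiDAR-derived tree metrics.

## What it does, and for whom

Forest biometricians estimating tree-level aboveground biomass (AGB) from
UAV LiDAR face two recurring problems. First, which allometric form should
relate a biomass component to LiDAR tree height (LH, m) and crown diameter
(LCD, m)? Second, models fitted per component (trunk, bark, branch, leaf)
predict a component sum that disagrees with a directly fitted total — the
*compatibility* problem. `fircompat` implements the full modelling chain:

1. **Base allometric forms** — logistic, linear, exponential, and power
   candidates, `BM = a·LH^b·LCD^c` and friends, fitted by
   Levenberg–Marquardt with analytic Jacobians and deterministic
   initializers, compared by AIC with a parsimony tie-break (within 2 AIC
   units, fewer parameters wins). Stepwise predictor screening and VIF > 5
   exclusion are included.
2. **Age-group dummy models** — five stand-development stages (young to
   over-mature) enter the power model as group-specific scale coefficients
   with shared exponents: `BM = (Σ b0i·AGi)·LH^b·LCD^c`.
3. **Additive NSUR system** — the four component equations are estimated
   jointly by nonlinear seemingly unrelated regression (iterated feasible
   GLS with the estimated 4×4 residual covariance), and the total is the
   *exact* sum of the component predictions: compatibility holds for every
   input by construction.

Evaluation metrics follow the field conventions used in the source tables:
R², RMSE with the **n − 1** denominator, absolute-deviation total relative
error TRE = Σ|y−ŷ|/Σy, and AIC/BIC from the concentrated Gaussian
likelihood. A seeded synthetic stand generator (`generate_stand()`)
reproduces the assumed data structure — per-group power-law means,
correlated multiplicative component errors, exact additivity — so the whole
pipeline is testable without the original (withheld) field data. The
published coefficient and summary tables ship verbatim
(`published_table()`), including flagged typographical defects.

## Worked example

```r
library(fircompat)

cfg   <- stand_config(n_per_age_group = rep(200L, 5L), seed = 42L)
stand <- generate_stand(cfg)                      # 1000 synthetic trees
sp    <- split_records(stand, frac = 0.7, seed = 43L)   # stratified 7:3

# compare the four base forms for trunk biomass
fits <- lapply(setNames(base_forms(), base_forms()),
               function(fm) fit_base(sp$train, fm, component = "trunk"))
rk <- rank_models(fits)
rk$table[, c("form", "k", "aic", "rank")]
#>         form k      aic rank
#>        power 3 4319.237    1
#>     logistic 4 4350.185    2
#>       linear 3 4781.573    3
#>  exponential 3 4786.392    4
rk$selected
#> [1] "power"
```

The power form wins on AIC (and would also win the parsimony tie-break
against the 4-parameter logistic if they were within 2 units). Adding the
age-group structure and then the compatible system:

```r
dummy <- fit_dummy(sp$train, "trunk", require_all_groups = TRUE)
sur   <- fit_nsur(sp$train)
sur
#> Additive NSUR biomass system (trunk + bark + branch + leaf = total)
#>   trunk  scales: 0.2099 0.1987 0.1907 0.2529 0.2434 | LH^1.8009 LCD^0.2054
#>   bark   scales: 0.1111 0.105 0.1003 0.1308 0.1263 | LH^1.4539 LCD^0.2047
#>   branch scales: 0.2916 0.2662 0.2617 0.3599 0.3451 | LH^1.1729 LCD^0.3083
#>   leaf   scales: 0.3428 0.3614 0.352 0.4673 0.445 | LH^0.9315 LCD^0.2399
#> n = 700, converged = TRUE after 4 outer iteration(s)
```

The fitted scales and exponents recover the generator's truth (the
published system coefficients, e.g. trunk 0.2124, 0.1964, ... with
exponents 1.8021 and 0.2035) to within sampling noise. Comparing base vs
dummy on identical data shows the age-group gain:

```r
compare_report(list(power = fits$power, dummy = dummy),
               sp$train, sp$test, "trunk")[, c("model","sample","r2","rmse","tre")]
#>  model sample     r2  rmse     tre
#>  power  train 0.9469 5.273 0.11592
#>  power   test 0.9519 4.732 0.10811
#>  dummy  train 0.9695 3.997 0.08276
#>  dummy   test 0.9708 3.687 0.08198
```

Predictions from the system are additive by construction — for a mature
(group 4) tree of LH = 14 m, LCD = 2.5 m:

```r
predict(sur, data.frame(lh = 14, lcd = 2.5, age_group = 4))
#>    trunk  bark branch  leaf total
#> 1 35.382 7.318 10.546 6.804 60.05
```

`total` is exactly `trunk + bark + branch + leaf` (60.05 kg here); the kg
components show the expected mature-stand allocation, trunk ≫ branch >
bark ≈ leaf.

## Package layout

* `R/` — synthetic generator, allocation equations, base/dummy/NSUR
  estimators, metrics, pipeline runner, published-table fixtures.
* `inst/extdata/` — the published tables, verbatim CSV.
* `inst/scripts/fircompat.R` — thin command-line wrapper
  (`simulate`, `run`).
* `vignettes/compatible-biomass-models.Rmd` — the methods vignette: model
  assumptions, estimator internals, generator calibration, numerical
  choices, limitations.
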