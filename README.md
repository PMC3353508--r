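# leafallom

Nondestructive estimation of eelgrass (*Zostera marina*) leaf biomass
converts easily measured leaf lengths into dry weights. The classical
plastochrone method does this with a constant leaf weight-to-length ratio —
implicitly assuming the **isometric** scaling *w = c·l*. `leafallom` is an R
package for deciding, on a given data set, whether that proxy is adequate or
whether the **allometric** power law

> *w = a·l^b*    (*w* dry weight in g, *l* length in mm, *a* > 0 the
> normalization constant, *b* > 0 the allometric exponent)

is required, and for quantifying exactly where the ratio proxy goes wrong.

For *b* ≠ 1 the two fitted curves intersect at the origin and at one
threshold length

> *l\** = (*c*/*a*)^(1/(b−1)),

and the deviation function θ(*l*) = *c·l* − *a·l^b* attains its maximum
absolute value inside (0, *l\**) at *l*<sub>θm</sub> = *l\**·*b*^(−1/(b−1)),
with closed form

> θ<sub>max</sub> = (*c*/(*a·b*))^(b/(b−1)) · *a* · |*b* − 1|.

When θ<sub>max</sub> is smaller than the residual standard errors of the
fits, the two models are practically indistinguishable below *l\**; beyond
*l\** (for *b* > 1) the ratio proxy systematically underestimates leaf
biomass, and the larger the share of leaves longer than *l\**, the larger
the aggregate bias.

The package provides:

* `fit_scaling()` — one fitting function for both models, on individual-leaf
  or shoot-aggregated data (`w_s = Σ_k a·l_k^b`), with standard errors,
  plus the usual methods (`summary`, `coef`, `predict`, `confint`,
  `residuals`, `simulate`, `plot`).
* `threshold_length()`, `max_deviation_length()`, `max_abs_deviation()`,
  `threshold_diagnostics()`, `bias_profile()` — the closed-form deviation
  analysis and the proxy's per-leaf bias profile.
* `compare_models()` — the full selection battery: R², Lin's concordance
  correlation coefficient, Gaussian AIC difference with the >4 / >10
  evidence bands, lack-of-fit F test against pure error, paired
  observed-vs-predicted means test, residual normality and
  homoscedasticity checks; serialisable via `write_report_json()`.
* `sim_config()`, `sim_preset()`, `simulate_leaves()`, `simulate_shoots()`,
  `recovery_experiment()` — a seeded synthetic-data generator
  (right-skewed lengths, heteroscedastic power-law weights, shoot
  aggregation) and parameter-recovery experiments.
* `read_leaf_csv()` / `read_shoot_csv()` and a thin command-line wrapper
  (`inst/cli/leafallom.R`) with `fit`, `diagnose`, `compare`, `simulate`
  and `recover` subcommands.

Units are fixed package-wide: millimetres and grams.

## Worked example

Simulate a population resembling a natural eelgrass meadow (power-law
weights, 20% of leaves beyond the threshold) and run the comparison:

```r
library(leafallom)
cfg <- sim_preset("san-quintin", n_leaves = 1000, seed = 2012)
leaves <- simulate_leaves(cfg)
cmp <- compare_models(leaves)
print(cmp)
```

```
Model comparison: allometric (w = a l^b) vs isometric (w = c l)
----------------------------------------------------------------
Allometric model
  parameters     : a = 1.09313e-05 +/- 8.61e-07, b = 1.39412 +/- 0.0134
  R^2 = 0.9081   CCC = 0.9518   se_fit = 0.00478   AIC = -10683.03
  lack of fit    : F(352,646) = 3.01, p = <2e-16
  means test p   : 0.936
  residuals      : normality p = <2e-16 (shapiro-wilk), homoscedasticity p = <2e-16
Isometric model
  parameters     : c = 0.00010454 +/- 8.97e-07
  R^2 = 0.8258   CCC = 0.8859   se_fit = 0.00658   AIC = -10045.60
  lack of fit    : F(353,646) = 7.33, p = <2e-16
  means test p   : <2e-16
  residuals      : normality p = <2e-16 (shapiro-wilk), homoscedasticity p = <2e-16
----------------------------------------------------------------
delta AIC (iso - allo) = 637.43  ->  strong (favours allometric)

Threshold diagnostics (isometric vs allometric)
  a = 1.09313e-05, b = 1.39412, c = 0.00010454
  threshold length l*        : 307.7 mm
  max-deviation length l_tm  : 132.4 mm
  max |deviation| theta_max  : 0.0039 g
  lengths below / above l*   : 86% / 14%  (n = 1000)

Bias profile of the isometric weight-to-length proxy
  n = 1000 leaves; threshold l* = 307.7 mm
  fraction underestimated (all leaves)  : 0.21
  fraction underestimated (l > l*)      : 0.62
  mean |relative miscalculation|        : 36.8%
```

Reading the output: the exponent estimate b ≈ 1.39 (truth 1.41) rules out
isometry; the AIC difference of 637 units is far beyond the "strong
evidence" band (>10), and the paired means test shows the allometric
predictions are unbiased (p = 0.94) while the isometric ones are not
(p < 1e-16). The fitted parameter pair implies a threshold of ~308 mm with
a maximum below-threshold deviation of only ~0.004 g — below the residual
standard errors of both fits, so the models agree for short leaves — but
62% of the leaves beyond the threshold are underestimated by the ratio
proxy. (Both models fail the normality and homoscedasticity checks here
because the generator's noise is multiplicative and lognormal by design.)

The closed-form diagnostics are also available directly, e.g. for the
published San Quintin parameter set:

```r
threshold_length(a = 0.00001, b = 1.410012, c = 0.0001)   # 274.7597 mm
max_abs_deviation(a = 0.00001, b = 1.410012, c = 0.0001)  # 0.003456045 g
```

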