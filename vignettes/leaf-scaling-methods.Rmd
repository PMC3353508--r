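---
title: "Methods: scaling models, threshold diagnostics and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scaling models, threshold diagnostics and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafallom)
```

## The two models and what is at stake

Eelgrass growth assessment by the plastochrone method converts leaf
elongation to biomass through a constant weight-to-length ratio of mature
leaf material. That conversion is exactly an isometric scaling assumption,

$$w = c\,l, \qquad c > 0 \;(\mathrm{g\,mm^{-1}}),$$

with $w$ the leaf dry weight (g) and $l$ the leaf length (mm). The
competing description is the allometric power law

$$w = a\,l^{\,b}, \qquad a > 0 \;(\mathrm{g\,mm^{-b}}),\; b > 0,$$

where $b \neq 1$ means the mass per unit length itself changes with leaf
size — as expected when longer leaves are also wider and heavier per
millimetre. The package fits both, compares them with a standard selection
battery, and, crucially, quantifies *where* they disagree through the
deviation function

$$\theta(l) = c\,l - a\,l^{\,b} \quad (b \neq 1), \qquad \theta \equiv 0
\text{ at } b = 1 .$$

For $b \neq 1$, $\theta$ vanishes at the origin and at the threshold
length $l_* = (c/a)^{1/(b-1)}$; on $(0, l_*)$ its magnitude peaks at
$l_{\theta m} = l_*\, b^{-1/(b-1)}$ with

$$\theta_{\max} = \left(\frac{c}{a\,b}\right)^{b/(b-1)} a\,\lvert b-1\rvert .$$

For $b > 1$, $\theta > 0$ below the threshold and $\theta < 0$ beyond it:
the ratio proxy *underestimates* every sufficiently long leaf, and the
bias grows without bound in $l$. For $b < 1$ the behaviour reverses; all
diagnostics handle both regimes. At $b = 1$ the threshold does not exist;
`threshold_length()` and `max_deviation_length()` raise a typed
`leafallom_undefined_threshold` error rather than returning infinity,
because every downstream consumer must branch explicitly on that case
(`max_abs_deviation()` returns 0 there, consistent with $\theta \equiv 0$).

$\theta(l_*) = 0$ and $d\theta/dl = c - a b\, l^{b-1} = 0$ at
$l_{\theta m}$ are exact closed-form identities; the test suite verifies
them to $10^{-10}$ relative and checks $\theta_{\max}$ against brute-force
grid maximisation of $\lvert\theta\rvert$ to $10^{-6}$ relative.

The threshold is extremely sensitive to $b$: since
$l_* = \exp(\log(c/a)/(b-1))$, a change of $b$ in the third decimal can
move $l_*$ by tens of percent when $b$ is close to 1. Published parameter
sets rounded to a few decimals therefore often fail to reproduce the
thresholds tabulated alongside them, even when $\theta_{\max}$ (much less
sensitive) reproduces cleanly. The package always computes $l_*$ from the
parameters as given and reports full precision, rounding only in display
blocks (1 decimal for $l_*$ in mm, 2 significant figures for
$\theta_{\max}$ in g).

## Fitting

`fit_scaling()` estimates either model at either data level. Units are
fixed package-wide (mm, g); readers reject other units by construction of
the column names rather than attempting autodetection.

**Raw scale (default).** The objective is unweighted additive least
squares on grams, the convention under which scaling parameters for these
data are normally reported. The isometric fit is the closed-form
regression through the origin $\hat c = \sum w_i L_i / \sum L_i^2$ (with
$L_i$ the leaf length, or the shoot's summed length at shoot level). For
the allometric model we exploit the same structure: *for fixed $b$* the
optimal normalization constant is closed-form,

$$a(b) = \frac{\sum_i w_i S_i(b)}{\sum_i S_i(b)^2}, \qquad
  S_i(b) = \sum_k l_{ik}^{\,b},$$

so the two-parameter problem collapses to a one-dimensional profile
minimisation over $b > 0$. We bracket the minimum with a coarse grid
(step 0.02) centred on the log–log regression starting value
(`loglog_start()`), expanding the bracket (up to $b \in [10^{-6}, 20]$) if
the minimum sits on an edge, then refine with `stats::optimize()`
(tolerance $10^{-9}$ in $b$). A minimum still on the boundary raises a
typed convergence error carrying the last iterate. This profiled search
minimises exactly the same objective as a two-dimensional Gauss–Newton
iteration but cannot diverge, needs no step-size control, and keeps
$a > 0$ automatically (weights are positive). The test suite confirms the
optimum against a dense grid in $b$ (step $10^{-4}$). Degenerate data
(all lengths identical) are rejected before optimisation.

Standard errors use the Gauss–Newton covariance
$\hat\sigma^2 (J^\top J)^{-1}$ with
$\hat\sigma^2 = \mathrm{rss}/(n - p)$, the `se_fit` residual standard
error reported alongside. Because leaf-weight scatter typically grows with
the mean, an HC3 heteroscedasticity-consistent covariance is also stored
(`vcov(fit, robust = TRUE)`); see *Calibration* below for why this
matters.

**Log scale.** `scale = "log"` fits ordinary least squares of $\log w$ on
$\log l$ — the maximum-likelihood estimator when errors are multiplicative
lognormal. Fitted values, residuals and `rss` are then on the log scale;
`coef()` still reports $(a, b)$ with $a = e^{\text{intercept}}$. At shoot
level the log fit regresses $\log w_s$ on $\log L_s$ and is an
approximation to the aggregated model, intended for sensitivity analysis
only.

Records with missing weight are excluded from fitting with a logged count;
they remain usable by length-only diagnostics such as the threshold
partition.

## The selection battery

`compare_models()` assembles, for each model: $R^2$ of observed against
predicted weights; Lin's concordance correlation coefficient
$\hat\rho = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$ with
$n$-denominator moment estimators (the original definition; an
$n{-}1$ variant is available and differs only through the squared
mean-difference term); the Gaussian least-squares AIC
$n \log(\mathrm{rss}/n) + 2K$ with $K$ counting the error variance
($K = 3$ allometric, $K = 2$ isometric) — additive likelihood constants
are dropped, so only within-dataset AIC differences are meaningful, and
the report therefore surfaces
$\Delta\mathrm{AIC} = \mathrm{AIC}_{\mathrm{iso}} -
\mathrm{AIC}_{\mathrm{allo}}$ prominently with the conventional evidence
bands (indistinguishable $\le 4$, positive $4{-}10$, strong $> 10$); a
lack-of-fit $F$ test; a paired two-sided $t$ test of observed versus
predicted means (the natural formalisation of "difference between
observed and projected means" on paired data); and residual normality and
homoscedasticity checks. The diagnostic p-values are reported raw — the
battery is descriptive, and adjusting across purposely different
hypotheses would make individual diagnostics uninterpretable; the report
says so in its output.

**Lack of fit.** Measured lengths are effectively discrete, so replicate
groups are formed by rounding lengths to a configurable resolution
(default 1 mm). With $m$ groups and $p$ mean parameters,
$SS_{\mathrm{pe}} = \sum_{\text{groups}} \sum (w - \bar w_{\text{group}})^2$,
$SS_{\mathrm{lof}} = \mathrm{rss} - SS_{\mathrm{pe}}$ (floored at 0), and
$F = [SS_{\mathrm{lof}}/(m-p)] / [SS_{\mathrm{pe}}/(n-m)]$ on
$(m - p,\; n - m)$ degrees of freedom, both reported with explicit labels.
Data without replicate groups yield a typed *not-applicable* result, not
an error — pure error is simply undefined there.

**Normality.** Shapiro–Wilk up to $n = 5000$ (its implementation limit);
beyond that the D'Agostino $K^2$ omnibus test, implemented from the
standard normalizing transforms of sample skewness and kurtosis (no
installed package provides it). **Homoscedasticity.** The studentized
(Koenker) Breusch–Pagan statistic $n R^2$ from the auxiliary regression of
squared residuals on fitted values, referred to $\chi^2_1$ — implemented
directly because the packaged versions test a linear model's residuals
against its own regressors, whereas here the residuals come from a
nonlinear fit and the single relevant regressor is the fitted value.

Degenerate inputs are handled explicitly throughout: identical
observed-and-predicted vectors give a means-test p of 1; constant nonzero
differences give p = 0 with a degeneracy flag; zero rss makes the AIC
diverge and raises a typed perfect-fit error instead of returning
$-\infty$; fewer than 8 residuals make the residual diagnostics
not-applicable.

## The synthetic-data generator

`sim_config()` describes a synthetic population; generation is driven by a
mandatory explicit seed, never by global RNG state (the caller's
`.Random.seed` is saved and restored), and identical configs produce
byte-identical datasets.

*What it emulates.* Right-skewed leaf-length distributions (lognormal by
default, median 150 mm, log-sd 0.5; gamma and uniform available);
power-law conditional means $a l^b$ with defaults $a = 10^{-5}$,
$b = 1.41$ of the magnitude reported for natural eelgrass meadows; and
heteroscedastic weight noise. The default noise is multiplicative
lognormal with $\sigma = 0.2$, mean-corrected by $e^{-\sigma^2/2}$ so that
$E[w \mid l] = a l^b$ exactly — the funnel-shaped spread this produces is
what makes raw-weight residuals fail homoscedasticity checks, as real
leaf data do. Additive and power-variance ($\mathrm{sd} \propto
\mathrm{mean}^\gamma$) noise are available; additive draws below zero are
truncated to a small epsilon and counted, with a warning when more than 1%
truncate (such a config is unrealistically noisy). Shoots draw their leaf
count uniformly from a configurable range (default 3–6, typical for
eelgrass) and sum their leaves' noisy weights.

`sim_preset()` ships four archetype populations mirroring the reported
below-threshold shares of the studied sites (80%, 70%, 82% and 20% of
leaves below $l_*$): each preset uses the site's published $(a, b)$ as
truth and places the lognormal length scale so that the share of lengths
below the threshold *implied by the published parameters* matches the
reported share. Nothing else about the sites' length distributions is
known, so nothing else is matched.

*What it does not emulate* — and hence what passing tests do and do not
show about real data: no leaf-age or rank structure (ranks are metadata
only), no within-shoot correlation of leaf sizes, no measurement error in
lengths, no temporal growth dynamics, no site-level parameter
heterogeneity beyond the preset means. Because the mesocosm-like preset
inherits the *published* mild curvature ($b = 1.1628$) and a threshold
implied by those rounded parameters (~996 mm, forcing an unrealistically
large median leaf), it reproduces the *direction* of the proxy's bias —
most leaves beyond the threshold underestimated, more than below it — but
not the ~80% underestimation share reported for the real mesocosm, whose
effective curvature was evidently stronger than the rounded printed
parameters convey. The tests assert the directional property only.

## Calibration of the recovery experiment

`recovery_experiment()` simulates replicate datasets (replicate $r$ uses
seed $\texttt{seed} + r$), fits each, and reports bias, relative bias,
RMSE and empirical coverage of nominal 95% intervals. Its
`fit_scale = "auto"` default matches the inference scale to the noise
model, and this is a deliberate statistical choice rather than a
convenience: under the default multiplicative lognormal noise, raw-scale
least squares remains nearly unbiased for $b$, but its *classical*
Gauss–Newton Wald intervals undercover severely (about 51% observed
coverage at $n = 500$, $\sigma = 0.2$; HC0 and HC3 sandwich intervals
reach only ~86% and ~91%), because the heavy-tailed length distribution
concentrates leverage in a few large, high-variance leaves. Log-scale OLS
is the correctly specified likelihood for that noise, so its $t$
intervals are exactly calibrated, and its normalization-constant estimate
is corrected by the lognormal smearing factor $e^{\hat\sigma^2/2}$ before
comparison with the generating value. Choosing `fit_scale = "raw"`
measures the undercoverage instead — both are honest experiments, about
different estimators. For additive noise, `"auto"` selects the raw scale,
whose classical intervals are then appropriate.

## Problem sizes used in validation

The shipped validation suite uses sizes at which the relevant asymptotics
are comfortably visible while the whole suite stays quick on a laptop:
parameter recovery with 200 replicates of $n = 500$ leaves; lack-of-fit
size with 2000 replicates of a 25-group × 4-replicate design and power
with 500 replicates of a 60 × 10 design ($n = 600$); end-to-end selection
with 100 replicates of $n = 1000$ leaves, where data generated with
$b = 1.4$ yield the strong AIC verdict in ≥95% of replicates; and the
grid cross-check of $\theta_{\max}$ on 100 random parameter triples with
$10^6$-point grids.

## Known limitations

* Unweighted least squares is the estimation convention; no
  variance-function weighting or measurement-error-in-length model is
  offered (the log-scale option covers the purely multiplicative case).
* No site-hierarchical or mixed-effects pooling: each dataset is fitted
  marginally.
* Threshold quantities are reported as point values; confidence intervals
  for $l_*$ and $\theta_{\max}$ (by error propagation or bootstrap) are a
  natural extension not currently implemented.
* The AIC convention drops additive constants, so values are not
  comparable across datasets or with other software's absolute AICs —
  only differences within a report are meaningful.
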