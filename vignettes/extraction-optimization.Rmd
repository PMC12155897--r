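---
title: "Optimizing extraction conditions: response surfaces and neural-network surrogates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing extraction conditions: response surfaces and neural-network surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desopt)
```

## The problem

Ultrasound-assisted extraction of polyphenols from plant material with a
deep eutectic solvent is governed by a handful of process factors — here
the liquid-to-solid ratio (mL of solvent per g of dry leaf), the ultrasonic
power (W) and the extraction time (min) — and a single response, the
polyphenol yield as a percent of dry mass. Running every factor combination
is infeasible, so the field's standard workflow is: run a small designed
experiment, fit a smooth model of the response surface, and optimize the
model instead of the process. `desopt` implements that workflow twice over
the same data — once with the classical second-order polynomial and once
with a small neural-network surrogate maximized by a genetic algorithm — so
the two optimization arms can be compared on equal footing.

The package ships a complete 17-run study of this kind (`agpl_runs()`,
`agpl_factors()`): a three-factor Box–Behnken design over 20–40 mL/g,
450–750 W and 30–50 min, with measured yields between 12.86% and 14.95%.
All documentation examples use it.

## The Box–Behnken design

A three-factor Box–Behnken design places runs at the 12 edge midpoints of
the factor cube (each pair of factors at their extremes, the third at its
center) plus replicated center runs; with the conventional 5 center
replicates that is 17 runs. Factor levels are *coded*: low/center/high map
to −1/0/+1 via half-range scaling,

$$x_i = \frac{X_i - X_{i,\mathrm{center}}}{(X_{i,\mathrm{high}} - X_{i,\mathrm{low}})/2}.$$

`bbd_design()` emits a deterministic run order (factor pairs in order, sign
combinations (−,−), (+,−), (−,+), (+,+), centers last). Least-squares
fitting is invariant to run order, so we do not randomize; a physically
executed design should of course be randomized by the experimenter. The
design is balanced: each factor's coded column sums to 0 and its squares
sum to 8, which gives the closed-form contrast estimators used as an
independent oracle in the test suite (linear coefficients are ±1-contrasts
divided by 8, interactions are four-point contrasts divided by 4, and the
intercept is the mean of the center runs).

## The quadratic model and its ANOVA

`fit_quadratic()` fits the full second-order polynomial in coded units,

$$y = b_0 + \sum_i b_i x_i + \sum_{i<j} b_{ij} x_i x_j + \sum_i b_{ii} x_i^2,$$

by QR-based ordinary least squares (10 coefficients; at least 10 runs with
responses are required, and collinear columns raise an explicit
singular-design error). `rsm_anova()` partitions the corrected total sum of
squares:

* per-term sums of squares are **partial (Type III)**, $SS_j = b_j^2/c_{jj}$
  with $c_{jj}$ the term's diagonal of $(X'X)^{-1}$. In a Box–Behnken
  design the pure-quadratic columns are not orthogonal to the intercept, so
  Type-III is the convention that standard response-surface software
  prints; sequential (Type I) sums of squares are available via
  `type = "sequential"`.
* **pure error** is the within-group variability of exact replicate runs
  (identical coded vectors); **lack of fit** is the residual remainder. Its
  F statistic uses the pure-error mean square. Designs without replicates
  drop these rows with a warning.
* summary statistics follow the usual definitions:
  $R^2 = SS_{model}/SS_{total}$, adjusted
  $R^2 = 1 - (1 - R^2)(n-1)/(n-1-p)$, and the coefficient of variation
  $CV\% = 100\sqrt{MS_{resid}}/\bar y$.

```{r anova}
fit <- fit_quadratic(agpl_runs(), agpl_factors())
glance(rsm_anova(fit))
```

On the packaged study this reproduces the published self-consistent ANOVA
cells (model F 8.92, adjusted $R^2$ 81.67%, CV 2.18%). A handful of
printed cells in the original report are internally inconsistent with its
own data (they fail the $SS$ additivity identities that every ANOVA must
satisfy); the package follows the data, and the test suite asserts the
conservation identities ($SS_{model}+SS_{resid}=SS_{total}$,
$SS_{lof}+SS_{pe}=SS_{resid}$) on every fit.

## Surface optima

`stationary_point()` solves $2Bx^\ast = -b$ exactly, where $B$ carries the
pure-quadratic coefficients on its diagonal and half the interactions off
it, and classifies the point by the eigenvalues of $B$ (all negative →
maximum). Eigenvalues within $10^{-10}$ of zero indicate a ridge: the point
is reported as a saddle with a warning, and a singular $B$ is an error that
advises the box-constrained search. `maximize_in_box()` handles the cases
the stationary point cannot: it seeds bounded quasi-Newton ascent
(`optim(method = "L-BFGS-B")`) from the best points of a $21^3$ grid, never
returns less than the grid maximum, and returns the box center for a flat
surface so the output is deterministic. Both optima are reported because a
fitted maximum can in general lie outside the experimental region, in which
case only the constrained answer is trustworthy. On the packaged study the
stationary point is interior (≈ 39.2 mL/g, 595 W, 40.7 min) and the two
coincide.

## The neural-network surrogate

`train_mlp()` implements a 3–H–1 multilayer perceptron: inputs and response
min–max normalized to $[-1,1]$, a hidden layer of hyperbolic-tangent
sigmoid units ($\mathrm{tansig}(x) = 2/(1+e^{-2x})-1$), and a linear
output. Normalization bounds always come from **all** runs, so a trained
network's predictions do not depend on which subset a point fell into.

Training is Levenberg–Marquardt: with $J$ the Jacobian of per-sample errors
with respect to all $5H+1$ parameters (computed by backpropagation), each
epoch applies $\delta = (J'J + \mu I)^{-1} J'e$, accepting the step and
dividing $\mu$ by 10 when the training SSE decreases, otherwise multiplying
$\mu$ by 10 and retrying. Stopping follows the conventional set of rules:
epoch cap (1000), training-MSE goal ($10^{-5}$, normalized scale), gradient
floor ($10^{-6}$), damping overflow, or `max_fail = 6` consecutive epochs
without a new validation minimum; the returned weights are those of the
best validation epoch. LM has no learning rate in the gradient-descent
sense; the initial damping defaults to $\mu_0 = 10^{-3}$ (the standard
choice) and is exposed as `mu_init` for users who want the more
conservative 0.1.

Design choices that were genuinely open:

* **Hidden size.** The default is $H = 7$, the minimum of the
  validation-MSE sweep on the packaged data (`neuron_sweep()`); with 36
  parameters against 12 training points this is deliberately
  overparameterized, which is the regime in which such surrogates are
  typically reported. `hidden` is an argument everywhere.
* **Splitting.** Each restart draws a fresh random 70/15/15
  train/validation/test partition (sizes by rounding with largest-remainder
  repair: 12/3/2 at $n = 17$) and fresh uniform$(-0.5, 0.5)$ initial
  weights. With 17 points the realized split dominates generalization, so
  restarts must vary it; the per-restart seeds are recorded and any run is
  exactly reproducible.
* **Restart selection.** `select = "validation"` (default) picks the
  restart with the lowest best-epoch validation MSE — the honest choice for
  prediction. `select = "all_r2"` picks by $R^2$ over all runs, which is
  the convention when a surrogate is judged on the full experiment, and is
  what the multi-restart acceptance analysis uses. With ≥ 50 restarts the
  best all-run $R^2$ on the packaged data is typically ≈ 0.98–0.99.

## Genetic-algorithm optimization

`ga_maximize()` searches the actual-unit factor box directly (the reported
optima are in actual units, and clipping to the box is the only constraint
handling): uniform initialization, tournament selection of size 2, BLX-0.5
blend crossover on an 0.8 fraction of offspring, per-gene Gaussian mutation
with probability 0.1 and standard deviation 10% of the gene's range, and
2 elites carried unchanged, for 300 generations over a population of 100.
The operator defaults (tournament-2, Gaussian mutation, BLX-0.5) are the
conventional real-coded choices; the numeric defaults follow the
methods-section parameter set of the packaged study, whose results section
quotes a different one (population 1000, mutation 0.2, 100 generations) —
every one of them is an argument, so either regime can be run. Elitism
makes the best-fitness trace non-decreasing, which the tests assert for
every seed, and a fixed seed reproduces the result bit-for-bit.
`fitness_from_surrogate()` plugs a trained network in as the fitness;
maximization is direct (no sign flip is exposed to the user).

## Model comparison

`model_metrics()` reports $R^2$ (one minus the residual-to-total ratio
around the observed mean), MSE with denominator $n$, RMSE $= \sqrt{MSE}$,
and two absolute-deviation statistics: `mad`, the mean absolute deviation
in response units, and `aad_pct`, the same deviation relative to each
observation in percent. Both circulate in the literature under the name
"AAD" and they differ by an order of magnitude on typical yield data, so
the package always reports both rather than guessing which one a reader
means.

## Assay calculators

* `polyphenol_yield()` is the Folin–Ciocalteu mass balance
  $Y = 100\,C V r / W$ (concentration from a gallic-acid calibration,
  extraction volume, dilution ratio, dry mass).
* `auc_curve()` is the ratio-sum area under a fluorescence-decay trace,
  $AUC = 1 + \sum_{i\ge 1} f_i/f_0$ — a plain ratio sum at uniform reading
  intervals, with no trapezoid correction, depending only on the ratios
  (scale invariance is tested).
* `orac_te()` subtracts the mean AUC of the radical-generator blank wells
  and converts sample net AUCs to Trolox equivalents. The primary path
  interpolates on the net-AUC-vs-Trolox calibration line, which is how such
  assays are normally reported; the single-point ratio against the
  standards is available as `method = "ratio"`. Negative equivalents are
  clamped to zero with a warning (a physical floor; tiny negative values
  from floating-point cancellation are clamped silently).

## Synthetic data with known answers

No raw instrument data accompanies the packaged study, so validation rests
on generators whose ground truth is known by construction:

* `sim_surface()` draws responses from exactly the model the
  response-surface analysis assumes — quadratic mean plus i.i.d. Gaussian
  error. At $\sigma = 0$ the fit must recover the generating coefficients
  to $10^{-10}$; at $\sigma = 0.1$ the RMS error of the linear coefficients
  must match the design's contrast standard error $\sigma/\sqrt 8$ (tested
  over 500 replicates within 20% sampling slack).
* `sim_calibration()` is a straight line plus Gaussian noise.
* `sim_plate()` builds decay traces shaped analytically (geometric decay
  with the ratio solved so the ratio-sum AUC hits its target exactly) so
  that sample net AUCs equal `slope * TE + intercept`; the ORAC pipeline
  must return the planted TE values exactly at zero noise. The decay shape
  is a free choice — the AUC statistic only sees ratio sums — and the
  generator's standards span 6.25–50 µM, the usual working range.

What these generators deliberately do **not** emulate: solvent chemistry
(viscosity, hydrogen bonding), heteroscedastic or drifting plate noise,
run-order effects, and model misspecification of the true response surface.
A passing recovery test therefore demonstrates correctness of the
estimators, not robustness of the assays to real-world artifacts.

## Problem sizes and numerical choices

The test-suite simulations use 100 random response vectors for the
fit-vs-contrast oracle, 500 replicates for the noise-scaling law, 20 random
concave quadratics for the GA-vs-analytic check, and 60 network restarts
for the multi-restart regime; these sizes give stable Monte-Carlo estimates
at desk scale. Other fixed numerical choices: ridge detection at
eigenvalue magnitude $10^{-10}$; stationary-system singularity at
$|\det B| < 10^{-12}$; flat-surface tie-break to the box center; replicate
grouping by exact coded-vector equality; design CSV round trips through
decimal text.

## Known limitations

* Only the 3-factor Box–Behnken design is constructed; central-composite
  and larger designs are out of scope, as are randomization/blocking.
* The ANOVA offers no multiple-testing adjustment, stepwise selection,
  transformations or prediction intervals.
* The published network weights of the packaged study were never printed,
  so its exact ANN metrics cannot be reproduced — only the operating regime
  (best-of-restarts all-run $R^2$) is, stochastically.
* The GA handles box constraints only, and the surrogate pipeline is
  single-response; multi-response desirability optimization is not
  implemented.
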