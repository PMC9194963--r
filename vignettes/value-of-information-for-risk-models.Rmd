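---
title: "Value of information for risk prediction models in development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value of information for risk prediction models in development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voidev)
```

## The decision problem

A binary risk threshold `z` converts a predicted risk into a treatment
decision, and encodes the harm–benefit trade-off of that decision: being
ambivalent at a predicted risk of exactly `z` means one true positive is
worth `(1−z)/z` false positives. Net benefit (NB) scores any treatment
rule on that common scale, in units of net true positives per patient,
with treat-none fixed at NB = 0 (the opt-in convention; the package
resolves predictions exactly at the threshold in favour of this default,
i.e. the treatment indicator is strict).

For a model developed on a finite sample, the predictions `π_i` are
uncertain in a specific sense: the *correct* model — the strongly
calibrated function returning each covariate pattern's true average risk
`p_i` — is unknown, and our knowledge of it given the development data `D`
is a posterior distribution. Conditional on one posterior draw of the
correct risks, the net benefits of the three available strategies (use the
model, treat all, treat none) and of the unattainable optimal rule (treat
exactly those with `p_i > z`) are computable on the development sample by
replacing observed outcomes with correct risks. The optimal rule's summands
are included exactly when positive, so per draw it dominates every
alternative — this per-draw dominance is what makes the EVPI exactly
nonnegative below.

Averaging over draws gives posterior-mean net benefits, and

* **EVPI(z)** = expected NB under perfect information minus the best
  expected NB under current information: the price of prediction
  uncertainty, on the NB scale;
* **relative EVPI(z)** = the ratio of the expected incremental NB (over
  the `max{0, NB̄_all}` baseline) under perfect versus current
  information. It is at least 1 where defined; it is `+Inf` when the
  model is not currently expected to add benefit but the correct model
  would (further development may be justified); and it is undefined when
  even the correct model adds nothing — the package returns `NA` for that
  case, assigned deliberately rather than arising from 0/0.

## Sampling the posterior of correct risks

`compute_voi()` integrates over the posterior by Monte Carlo. Each draw
re-runs the *entire* model-development process — including any variable
selection and cross-validated shrinkage — on a reweighted version of the
data, then applies the refitted model to the original sample:

* **ordinary bootstrap**: multinomial weights, equivalently resampling `n`
  rows with replacement (and implemented exactly as resample-then-refit);
* **Bayesian bootstrap**: Dirichlet(1, …, 1) weights built from `n − 1`
  ordered uniforms, a posterior draw under a noninformative prior; this
  requires developers to accept continuous case weights, which all the
  built-in developers do;
* **likelihood-based MVN**: coefficient draws from the multivariate normal
  defined by the logistic MLE and its covariance — the parametric
  alternative when the development process is a plain logistic fit.

Cross-validation folds inside a developer are re-randomized in every draw,
so fold-assignment variability is propagated along with selection and
shrinkage uncertainty.

A resample with fewer than `min_events` events (or no non-events) cannot
support model development and is redrawn, up to `max_redraws` times;
persistent failures are excluded from the posterior means and reported in
the diagnostics, never silently dropped. The default guard is 1 event for
generic use; sample-size sweeps use a dataset-level guard of 8 events by
default, because penalized-likelihood optimizers are unreliable below
that.

Reproducibility: one master seed is expanded into per-draw substream
seeds, so draw `i` is bit-reproducible regardless of execution order, and
the joint EVPI + optimism loop is exactly identical to running the two
procedures separately with the same seed.

## Numerical choices

EVPI is reported per threshold as `min(M_max, D_model, D_all)`, where
`M_max` is the mean over draws of the perfect-information NB and
`D_model`, `D_all` are means of the *paired per-draw differences* against
the model and treat-all strategies. In exact arithmetic this equals the
defining expression `NB̄_max − max{0, NB̄_model, NB̄_all}`. The paired
differences are accumulated as sums of their sign-definite summands
(clamped at zero, where they can differ from the exact value only by
rounding noise at the treatment boundary), so `evpi ≥ 0` holds exactly in
floating point, draw by draw — not merely in expectation. The exported
`nb_*` functions, by contrast, use the plain textbook formulas. Ties in
`max{0, NB̄_model, NB̄_all}` are resolved toward the simpler strategy
(none, then all, then model), so the model is credited only when strictly
better.

Monte Carlo standard errors are reported for every posterior mean; the MC
SE of EVPI is that of the paired difference against the selected
current-information strategy. A warning fires when it exceeds 10% of the
EVPI, following the rule of thumb that the number of draws should make MC
error small relative to the estimate; the default is 1000 draws.

The threshold grid defaults to 0–0.99 in steps of 0.01. `z = 1` is outside
the domain (the exchange rate diverges), and run configurations reject
thresholds above 0.99 before any computation.

## Developers and refit stability

The `model_developer` contract carries the whole development process into
the resampling loop. Built-ins: `lasso_developer()` (10-fold
cross-validated lasso, the default for the pipeline), `ridge_developer()`
(fixed L2 penalty), `logistic_developer()` (unpenalized ML),
`intercept_developer()`, and test doubles (`constant_developer()`,
`point_mass_developer()`, `oracle_developer()`).

Refit stability matters more inside the loop than for a single fit. Two
failure modes are worth knowing:

* unpenalized logistic refits on resamples of a rare outcome can
  quasi-separate, producing essentially unbounded coefficient draws whose
  saturated predictions inflate the EVPI at extreme thresholds — and they
  do so more under the ordinary bootstrap (which deletes ~37% of rows per
  resample) than under the all-positive Dirichlet weights;
* cross-validating a penalty on an ordinary-bootstrap resample leaks
  duplicated rows between training and validation folds, biasing the
  selected penalty downward.

For comparisons *between sampling schemes* we therefore use the
fixed-penalty `ridge_developer()`, which is stable under both weighting
schemes and has no fold randomness; with it the ordinary and Bayesian
bootstraps agree within Monte Carlo error at every threshold, which is the
behaviour the theory predicts for the scheme itself.

## Optimism correction

`harrell_correct()` implements the classical bootstrap optimism estimate:
per replicate, the refitted model's metric on its own bootstrap sample
minus its metric on the original sample, averaged, then subtracted from
the apparent value. NB optimism is computed and corrected pointwise per
threshold (no smoothing); the c-statistic uses midranks (ties count ½).
Harrell's estimator is defined for resamples, so the correction — and the
joint loop — always uses the ordinary bootstrap, even when EVPI itself is
computed with Dirichlet weights. A data-independent developer has exactly
zero c-statistic optimism; its NB optimism is exactly zero wherever its
constant prediction treats nobody, and mean-zero otherwise.

## The synthetic truth

`logistic_dgp()` defines a known logistic truth: per-predictor marginal
distributions (normal or binary), optional transforms applied before the
linear predictor — truncation `min(x, cap)` and a one-knot linear spline
`(x, max(0, x − knot))` — and one coefficient per basis column. Generated
samples expose the transformed, model-ready columns; the true risks are
returned separately and never enter the developer interface, so no fitting
path can consume them accidentally.

The preset `gusto_like_dgp()` emulates the structure of a post-MI
30-day-mortality development setting: a ~7% marginal event rate (the
intercept was calibrated numerically once, by root-finding on a large
fixed covariate sample), an age-like predictor, a blood-pressure-like
predictor truncated above 100 (so its effect is confined to the
hypotensive range), a pulse-like predictor with a spline knot at 50, and
four binary comorbidity indicators of which two are pure noise — chosen to
exercise every transform and give the lasso something to select away. The
coefficients are package defaults on plausible clinical scales, not
estimates from any real trial. What passing tests on this truth shows is
that the machinery behaves correctly under a realistic rare-outcome,
mixed-predictor regime; it does not validate the method against real
registry data, which have missingness, measurement error and model
misspecification the DGP does not emulate.

Problem sizes used in the shipped checks are deliberately modest — e.g.
50 random datasets of n ≈ 80–200 for the nonnegativity sweep, n = 1000
with 500 draws for the scheme comparison, and sizes 250/1000/4000 with 10
replicates and 200 draws for the sample-size trend — enough for each
property to be decided by its own Monte Carlo error bars.

## Known limitations

* The EVPI here measures the cost of *parameter* uncertainty from the
  finite development sample — not the value of knowing individual
  outcomes, and not transportability to an external population
  (validation-phase value of information is a distinct quantity and out of
  scope).
* The Bayesian interpretation assumes the development process's implied
  model family can represent the correct model; with badly misspecified or
  black-box developers the posterior of correct risks inherits that
  misspecification.
* Missing-data handling is intentionally absent: inputs with missing
  values are rejected rather than imputed. Imputation inside the draw loop
  is a natural extension but is not implemented.
* Expected value of sample information (how much a *specific* additional
  study would help) is not computed.
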