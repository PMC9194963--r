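# voidev

Value-of-information analysis for clinical risk prediction models at the
development stage.

## The problem

A risk prediction model developed on a finite sample gives uncertain
predictions: a different development sample would have produced a different
model and, for some patients, a different treatment decision. `voidev`
quantifies what that uncertainty *costs* on the decision-analytic scale used
to evaluate risk models — net benefit (NB) at a risk threshold `z`,

    NB(z) = P(true positive) − P(false positive) · z/(1−z),

where `z/(1−z)` is the exchange rate between false- and true-positive
classifications (at `z = 0.02`, a true positive is worth 49 false
positives).

Adopting a Bayesian view, the unknown *correct* model (the strongly
calibrated model returning each patient's true average risk `p_i`) has a
posterior given the development data. Replacing observed outcomes with
correct risks gives, per posterior draw and threshold,

    NB_model(z; θ) = (1/n) Σ 1(π_i > z) [p_i − (1−p_i) z/(1−z)]   (use the model)
    NB_all(z; θ)   = (1/n) Σ            [p_i − (1−p_i) z/(1−z)]   (treat everyone)
    NB_max(z; θ)   = (1/n) Σ 1(p_i > z) [p_i − (1−p_i) z/(1−z)]   (treat by correct risk)

with `π_i` the proposed model's predictions. Averaging over posterior draws
and comparing the best achievable strategy against the best currently
identifiable one gives the **expected value of perfect information**:

    EVPI(z) = NB̄_max(z) − max{0, NB̄_model(z), NB̄_all(z)}

and the **relative EVPI**, the ratio of the expected incremental NB (over
the treat-none/treat-all baseline) under perfect versus current
information. A large EVPI says prediction uncertainty is expensive: a
larger development sample is warranted before the model advances to
validation.

Posterior draws of the correct risks are generated by re-running the entire
model-development process — including variable selection and shrinkage — on
bootstrap-weighted data (ordinary or Bayesian/Dirichlet bootstrap), or by
multivariate-normal coefficient sampling around the logistic MLE. The same
resampling loop doubles as Harrell's bootstrap optimism correction for the
decision curve and c-statistic.

## Worked example

A synthetic development sample in the regime of a post-MI mortality model
(n = 1000, ~7% event rate, seven candidate predictors with truncation and
spline transforms), developed with cross-validated lasso — the development
process is re-run inside every one of 500 bootstrap draws:

```r
library(voidev)
gen <- generate_sample(gusto_like_dgp(), 1000, seed = 42)   # 67 events
res <- compute_voi(gen$sample, lasso_developer(), n_draws = 500,
                   scheme = "ordinary_bootstrap", seed = 1)
print(res)
```

```
Value-of-information analysis (ordinary_bootstrap)
  n = 1000 | draws used = 500 | failed = 0
 threshold nb_model_bar nb_all_bar nb_max_bar      evpi evpi_r best_current
      0.01     0.057015    0.05702  0.0570832 6.784e-05    Inf          all
      0.02     0.047461    0.04739  0.0478706 4.094e-04  7.000        model
      0.05     0.025193    0.01731  0.0268639 1.671e-03  1.212        model
      0.10     0.011730   -0.03728  0.0134882 1.758e-03  1.150        model
      0.20     0.004038   -0.16694  0.0054516 1.414e-03  1.350        model
      0.50     0.000000   -0.86711  0.0006266 6.266e-04    Inf         none
```

Reading the `z = 0.02` row: under current information the best strategy is
to use the model, worth 0.00007 net true positives per patient over
treating everyone; knowing the correct model would be worth 0.00048 —
an EVPI of 0.0004 and a relative EVPI of 7, i.e. the correct model is
expected to deliver several times the incremental benefit of the proposed
one, so at this sample size uncertainty is still consequential. At
`z = 0.01` the model is not (yet) expected to beat treating everyone
(`best_current = all`, relative EVPI `Inf`); at `z = 0.50` no strategy
beats treating no one.

Optimism correction shares the same machinery (or one joint loop via
`joint_loop()`):

```r
rep <- harrell_correct(gen$sample, lasso_developer(), n_boot = 200, seed = 1)
#> c-statistic: apparent 0.698, corrected 0.670
```

`sample_size_sweep()` repeats the analysis across development sample sizes
to show how EVPI shrinks as data accumulate, and
`run_evpi_command()`/`inst/cli/voidev.R` expose the pipeline for CSV inputs
from the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/voidev.R", package = "voidev"))')" \
  evpi --input sample.csv --n-draws 1000 --scheme bayesian_bootstrap --output-dir out/
```

which writes `voi_results.csv` (one row per threshold; `Inf` relative EVPI
serialized as `Inf`, the undefined case as an empty field) and
`diagnostics.json`.

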