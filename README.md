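# dyncpm

Dynamic connectome-based predictive modeling of continuous emotional
arousal.

## What this package is for

During naturalistic fMRI (people watching movies in the scanner),
emotional arousal rises and falls continuously. A long-standing
question in affective and network neuroscience is whether those
moment-to-moment fluctuations are readable from the brain's
*dynamic functional connectivity* — the time-resolved correlation
structure among regions — rather than from regional activity alone.
`dyncpm` implements the full analysis pipeline for that question as a
tested, reusable R package, for researchers who have (or simulate)
ROI-level BOLD time series and continuous behavioral ratings:

* continuous 1–25 slider ratings → resampled, z-scored, group-averaged,
  HRF-convolved, taper-smoothed **group arousal target**, with
  leave-one-out intersubject correlation (ISC) and a sign-flip null;
* ROI × time BOLD matrices → **tapered sliding-window dynamic FC**:
  for every ROI pair and TR, the Fisher-z weighted Pearson correlation
  within a Gaussian-tapered window (σ = 3 TR, one window per TR);
* **CPM**: edges whose FC tracks the target across training subjects
  (one-sample t-test on Fisher-z correlations, p < .01) feed a
  radial-basis support vector regression, evaluated by
  leave-one-subject-out cross-validation; fold accuracies are
  summarized as tanh(mean(atanh r)); the edges selected in *every*
  fold with a consistent sign form the **arousal network**;
* **across-dataset generalization**: a model trained on one dataset's
  arousal network predicts a different group watching a different
  movie;
* **null models**: phase-randomized surrogate targets (within-dataset
  nulls are positively skewed by design; across-dataset nulls center
  on zero), circular-shift nulls, TOST equivalence tests,
  permutation p-values with the add-one formula;
* **network anatomy**: signed edge sets, hypergeometric overlap test
  `P(X > x)` on the 7381-edge connectome, Jaccard similarity with a
  shuffle null, and 8-network pair enrichment with permutation + FDR;
* a **synthetic-data generator** that plants a known arousal-coupled
  edge set (shared components with analytically exact time-varying
  correlation), simulates noisy step-function raters and nuisance
  series, so every stage is testable end to end with ground truth.

## Worked example

Simulate a dataset with a planted arousal network, build the target
from the simulated raters, fit the LOSO CPM, and compare it with a
phase-randomized null:

```r
library(dyncpm)

cfg <- synth_config(n_subjects = 8, n_roi = 20, n_tr = 300,
                    n_planted = 6, coupling = 0.8, seed = 42)
ds  <- simulate_dataset(cfg, window_s = 45)

target <- build_group_target(ds$ratings, ds$spec)$smoothed
fcset  <- dynfc_set(ds$bold, ds$spec)

fit <- run_loso(fcset, target, alpha = 0.01)
fit
#> Leave-one-subject-out CPM: 8 subjects, alpha = 0.01
#>   mean r (Fisher-z averaged): 0.276
#>   mean RMSE:                  0.972
#>   consensus edges:            2 (0 sign conflicts)

nul <- build_prediction_null(fcset, target, n_perm = 50, seed = 1,
                             mode = "within")
permutation_pvalue(fit$mean_r, nul$r, "greater")
#> [1] 0.01960784

# the consensus network is a subset of the planted edges
fit$consensus$edge
#> [1]  89 148
sort(ds$truth$planted$edge)
#> [1]   8  89 123 148 158 185
```

Here the model predicts the held-out subjects' arousal target at a
Fisher-z mean r of .28 per fold; that accuracy exceeds all 50
within-dataset surrogate fits (p at the permutation floor, 1/51).
At this deliberately small scale the fold-intersection consensus is
conservative — it keeps 2 edges, both genuinely planted; the larger
recovery experiment in the test suite (16 subjects, 60 ROIs, 500 TRs)
recovers the full planted set. `tidy()`, `glance()` and `autoplot()`
methods give per-fold tibbles, one-row summaries, and diagnostic
plots for every fitted object.

## Design notes

The methods vignette (`vignettes/dyncpm-methods.Rmd`) documents the
model conventions and the reasoning behind them: windowing and
weighting choices, transform order for the behavioral target, Fisher-z
conventions and clipping, SVR hyperparameters and training-row
thinning, null-model construction, and the generator's scope and
limitations.
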