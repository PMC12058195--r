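---
title: "Predicting continuous arousal from dynamic connectivity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting continuous arousal from dynamic connectivity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyncpm)
```

# The problem

During naturalistic stimulation (watching a movie in the scanner),
emotional arousal fluctuates continuously. `dyncpm` implements a
connectome-based predictive modeling (CPM) pipeline that asks whether
those fluctuations can be decoded from *dynamic functional
connectivity* (FC): the time-resolved correlation structure among
brain regions. The pipeline has five stages, each usable on its own:

1. **Behavior** — continuous 1–25 slider ratings from a panel of
   raters are resampled to the fMRI TR grid, z-scored, averaged into a
   group target, convolved with a hemodynamic response function, and
   smoothed with the same tapered window as the connectivity stream.
2. **Dynamic FC** — per subject, the Fisher-z weighted Pearson
   correlation of every ROI pair inside a Gaussian-tapered sliding
   window, one window per TR.
3. **CPM** — edges whose FC series correlate with the target across
   training subjects (one-sample t-test, p < .01) feed a radial-basis
   support vector regression, evaluated with leave-one-subject-out
   (LOSO) cross-validation and across-dataset transfer.
4. **Null models** — phase-randomized surrogate targets, circular
   shifts, sign flips, and equivalence (TOST) tests.
5. **Network anatomy** — signed edge sets, hypergeometric and Jaccard
   overlap tests, and network-pair enrichment with permutation + FDR.

Everything is exercised on synthetic data with *planted* ground truth,
so recovery can be verified exactly.

# The synthetic generator

The generator emulates the statistical structure the analysis assumes,
not the biophysics of BOLD.

**Latent state.** Gaussian white noise convolved with a Gaussian
kernel (sd `smoothness_tr`, default 10 TRs) and z-scored. The kernel
sd is the single autocorrelation knob; 10 TRs (15 s at TR = 1.5 s)
gives excursions on the timescale of scenes rather than frames.

**Planted edges.** A set of ROI-disjoint pairs receives a shared
standard-normal component with time-varying amplitude
$a(t) = \sigma \sqrt{\rho(t) / (1 - \rho(t))}$, so the instantaneous
model correlation of the pair is exactly
$\rho(t) = 0.9\,c\,\mathrm{logistic}(z(t))$, where $z$ is the latent
state and $c \in [0, 1]$ the coupling gain. The 0.9 ceiling keeps the
Fisher-z transform well away from its singularity. ROI-disjointness is
what makes $\rho(t)$ analytically exact; it is also why the generator
requires `2 * n_planted <= n_roi`. The default coupling of 0.6 is a
test-convenience choice — the empirical coupling between arousal and
FC in real data is unknown — and the recovery experiments use 0.8.

**Raters.** Each rater is a right-continuous step function on the
integer 1–25 scale: the latent state rescaled to the slider range,
plus AR(1) noise (stationary sd `rater_noise_sd`, lag-1 0.5 between
presses), updated at Poisson press times (default 6 presses/minute,
about one press per 10 s, a realistic slider cadence), rounded half
away from zero and clipped. Quantization, press sparsity, and noise
are the three ways a rater panel degrades the target.

**Nuisance series.** Ten low-level stimulus features (six continuous,
four 0/1 indicators) and a non-negative framewise-displacement series
per subject. The optional leak mode replaces feature 1 with a
white-noise series whose *amplitude* is modulated by the latent state.
Injected into every ROI, such a series inflates windowed correlations
in proportion to arousal — a genuine FC confound — and, because the
feature records the confound itself, OLS residualization removes it
exactly. A purely additive `latent + noise` regressor could not play
this role: with amplitude-coupled edges, additive confounds do not
create arousal-locked correlation changes in the first place.

**What the generator does not emulate:** hemodynamic lag in the BOLD
stream (the planted correlations follow the latent state directly),
scanner noise spectra, spatial autocorrelation among ROIs, or
physiological confounds beyond FD. Passing recovery tests therefore
shows that the *pipeline* is correct and well-calibrated, not that
real BOLD data carry the signal.

**Determinism.** One master seed; subjects, raters, and features draw
from fixed sub-streams (`derive_seed()`), so adding a 17th subject
does not perturb the first 16. All generators save and restore the
global RNG state.

# Behavioral target: conventions

* **Resampling.** The slider value assigned to TR $k$ is the value
  prevailing at the *end* of the interval $[k\,\mathrm{TR}, (k+1)\,
  \mathrm{TR})$ (last value carried forward). The choice of interval
  endpoint is not dictated by anything in the task; end-of-interval
  is used consistently and is configurable by preprocessing the event
  times.
* **Order of transforms.** z-score → HRF-convolve → taper-smooth.
  z-scoring before convolution matches the order in which the stages
  are described in the modeling literature this pipeline follows; the
  two orders differ only by an affine map when the convolution kernel
  is fixed, and the correlation-based accuracies used downstream are
  invariant to affine maps of the target.
* **HRF.** The canonical double-gamma (response gamma shape 6, rate 1,
  peaking at 5 s; undershoot gamma shape 16, rate 1, weight 1/6),
  sampled on the TR grid, causal, truncated at 32 s.
* **Taper.** Gaussian weights (sd 3 TRs) on a window of `window_tr`
  TRs (30 TRs = 45 s at TR 1.5 s), renormalized where the window is
  cropped by the series boundary. The same weights define the
  windowed correlation, which keeps the behavioral and connectivity
  streams on one timescale and one grid (both have exactly one value
  per TR).
* **ISC.** Leave-one-out intersubject correlation summarized by the
  Fisher-z mean; perfect correlations are clipped to
  $1 - 10^{-15}$ before `atanh`. The sign-flip null is one-tailed
  (tests mean ISC > 0) with the add-one formula, so its p-value can
  never drop below $1/(n_{\mathrm{perm}}+1)$. One honest caveat,
  verified by simulation in the test suite: leave-one-out
  similarities are positively inter-correlated, which the flip null
  ignores, so the test is mildly anti-conservative (long-run type-I
  rate near 11% at the nominal 5% level for white-noise panels).
* **Valence segments.** Positivity keeps TRs with raw group mean
  strictly above the neutral 13, negativity strictly below; TRs at
  exactly 13 belong to neither. Retained TRs are concatenated and
  sent through the same z-score → HRF → taper chain.

# Dynamic FC: conventions

* Windows are *centered* on each TR with boundary truncation, giving
  exactly one output column per input TR and aligning the FC stream
  with the taper-smoothed target.
* The within-window correlation is *fully weighted* (weighted means
  and variances), not an unweighted correlation over a masked window:
  a Gaussian-tapered window is a weighting scheme, so the weights
  belong inside the estimator.
* Correlations are clipped to $\pm(1 - 10^{-7})$ before `atanh`.
  Zero-variance window cells become 0 with a counted warning rather
  than `NaN`, so downstream selection never has to handle missing
  cells.
* Window lengths in seconds convert to TRs by `round(sec / tr_s)`;
  the sweep helper accepts the usual {15, 30, 45, 60, 75} s grid.
* ROI and TR indices are 1-based throughout, following R convention.

# CPM: conventions

* **Selection** uses the per-subject Pearson correlations between
  each edge's Fisher-z FC series and the target, Fisher z-transformed
  (variance stabilization; a toggle reverts to raw r), then a
  one-sample two-tailed t-test across training subjects at
  $\alpha = .01$. The held-out subject never enters selection or
  training; the LOSO driver computes each subject's edge–target
  correlations once and forms each fold's t-test from the other
  $N-1$ columns, which is arithmetically identical to selecting from
  scratch per fold.
* **Regressor**: `e1071::svm` eps-regression with a radial-basis
  kernel and library defaults (C = 1, ε = 0.1, γ = 1/n features on
  features standardized by training-set statistics only). No
  hyperparameter search.
* **Training-row thinning.** Consecutive tapered windows overlap by
  all but one TR, so the stacked training windows are massively
  redundant. The trainer thins them to at most `max_train_rows = 600`
  evenly spaced rows (deterministic). At the window lengths used here
  this leaves accuracy unchanged (checked against caps of 400–1000)
  while keeping the quadratic-cost SVR fast enough for
  permutation-null loops.
* **Scores.** Accuracy is Pearson r per fold, summarized by
  $\tanh(\mathrm{mean}(\mathrm{atanh}\,r))$; a constant prediction is
  recorded as r = 0 with a degeneracy flag. RMSE is computed after
  z-scoring the prediction with its own statistics (the target is
  already on the z scale), with a raw-scale toggle.
* **Consensus network**: edges selected in every fold with a
  consistent sign; edges whose sign flips across folds are dropped
  and counted. The target is tiled identically for every training
  subject — only group-level ratings exist.
* **Degenerate fits.** A (near-)constant training target leaves no
  support vectors; the model then predicts the constant mean rather
  than crashing.

# Null distributions

* **Phase randomization** keeps the amplitude spectrum exactly
  (conjugate-symmetric uniform phases; DC and Nyquist untouched), so
  surrogates preserve mean, variance, and autocorrelation while
  destroying temporal alignment.
* **Within-dataset nulls** train *and* test on the same surrogate: the
  model may learn arbitrary stimulus-locked FC structure correlated
  with that surrogate, so this null is positively skewed — the
  appropriate, conservative baseline for within-dataset accuracy.
* **Across-dataset nulls** randomize the training target and score
  against the true test target (a toggle randomizes both sides);
  surrogate-trained models have nothing that generalizes, so this
  null centers on zero. The asymmetry between the two nulls is itself
  a property the test suite reproduces.
* **Permutation p-values** use the add-one formula with ties counted
  as exceedances (`>=`), the conservative convention consistent with
  a floor of $1/(n+1)$.
* **Circular-shift nulls** exclude the zero shift and draw shifts
  without replacement once `n_perm` reaches the number of distinct
  shifts.
* **TOST** equivalence runs on Fisher-z fold accuracies with the
  bounds transformed accordingly (default ±0.1 on the r scale); a
  raw-scale toggle exists. Bounds must be finite.

# Network anatomy

* The hypergeometric overlap test implements the literal
  survival-function form $P(X > x)$ by default, with an
  `inclusive = TRUE` flag for the conventional $P(X \ge x)$; the two
  differ by one probability mass point, invisible at connectome scale
  but visible on toy instances.
* The Jaccard null re-draws *both* sets' edge positions with sizes
  fixed (exchangeable treatment of the two networks); a single-set
  toggle exists.
* Network-pair enrichment covers all 36 unordered pairs of the 8
  canonical networks (8 within + 28 between), with one-tailed
  permutation p-values and BH-FDR within each sign's family of 36.
  The permutation count must satisfy
  $36/(n_{\mathrm{perm}}+1) \le q$ for the floor to be able to
  survive correction; the default 10000 does comfortably, 100 does
  not.
* The shipped 122-ROI-to-8-network table is *synthetic* (realistic
  network sizes, 8 subcortical ROIs) and exists so simulated 122-ROI
  data can exercise the anatomy stage; it is not a published atlas
  assignment.

# Problem sizes in the test suite

The recovery experiments run at 16 subjects × 60 ROIs (1770 edges) ×
500 TRs with 20 planted edges and coupling 0.8, a scale chosen so a
planted network is comfortably detectable while a full LOSO fit with a
100-iteration phase-randomized null completes in minutes on a single
core. Calibration checks (selection at coupling 0) use 19-iteration
nulls across 20 generator seeds — the smallest null for which
rejection at the 5% level is still possible — and the cross-dataset
experiments use 10-subject, 40-ROI, 300-TR dataset pairs with the
planted-edge overlap set to 100% or 0%.

# Known limitations

* The generator's BOLD stream carries the latent state without
  hemodynamic lag, while the target chain applies the HRF; the small
  resulting misalignment (≈3 TRs against a 30-TR window) slightly
  depresses measured accuracies. Real data would have the lag on the
  brain side instead.
* The sign-flip ISC null is mildly anti-conservative (see above).
* Planted edges are ROI-disjoint; real arousal networks share hubs.
* The SVR is the only learner; the design isolates the regressor
  behind `cpm_hyperparams()` + `fit_predict()`, which is the natural
  extension point.
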