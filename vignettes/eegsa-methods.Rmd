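---
title: "Identifying at-risk situation awareness from EEG band ratios: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying at-risk situation awareness from EEG band ratios: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegsa)
```

## The problem

Operators of safety-critical systems — ship pilots navigating in poor
visibility are the motivating case — can drift into a low
situation-awareness (SA) state in which they perceive, comprehend and
project the environment poorly. EEG band-power ratios are a standard
physiological proxy for this state: relative increases in slow (theta,
alpha) over fast (beta) activity in frontal (F) and central (C) regions
accompany disengagement. `eegsa` implements a complete identification
pipeline around this idea:

1. **Spectral features.** Per 1 s sub-epoch and per region, a DFT-based
   power spectral density is reduced to band powers (delta, theta, alpha,
   beta, gamma) and to five ratio metrics: θ/β, α/β, θ/(α+θ), (α+θ)/β and
   (α+θ)/(α+β). A 5 s sliding window (50% overlap by default) summarises
   each metric by its within-window mean and median, producing named
   features (`FM1`, `FP1`, ...; `M` mean, `P` median, index = metric rank).
2. **Screening.** Per (metric, region), subject-level means of the two SA
   groups are compared with Welch's *t* and a two-sided permutation test;
   pairs significant at the lenient 0.1 level in F/C are expanded into the
   mean/median feature set.
3. **Random-forest reduction.** A grid-searched random forest ranks
   features by out-of-bag (OOB) noise-injection importance; backward
   elimination scored by a normalised RMSE selects the retained subset.
4. **PCA combination.** Correlation-matrix PCA of the retained features;
   components are kept up to 87.7% cumulative variance contribution, and
   composite weights `w_k = contribution_k / sum(contributions[1:k])`
   summarise their relative importance.
5. **PCA-fused CNN.** Component scores of consecutive same-subject epochs
   are stacked into 13 × 20 maps and classified by a small convolutional
   network whose pooling output is augmented, point by point, with a
   frozen principal-subspace projection of the convolution output.
6. **Evaluation.** Confusion-based metrics (ACC, TPR, TNR, MCC, F1,
   Cohen's kappa) and rank-based ROC/AUC, with a harness comparing the
   plain random forest, the plain CNN and the hybrid.

The positive class throughout is **low SA** — the at-risk state the
pipeline is built to detect.

## Spectral conventions

The PSD uses the normalisation `S(w) = (Δt² / NΔt) |X(w)|²` with
`Δt = 1/fs`; `dft()` is the plain unnormalised forward DFT. Under this
convention `Σ_w S(w) = Δt Σ_t x(t)²`, which the test suite asserts as an
algebraic identity. Band powers sum `S(w)` over positive-frequency bins
below Nyquist only, with DC excluded.

The conventional integer band edges (1–4, 5–8, 9–14, 15–30, 31–59 Hz)
leave 1 Hz gaps; on the 0.2 Hz grid of a 5 s epoch those gaps would
silently drop bins. The package therefore treats bands as contiguous
half-open intervals `[lo, hi+1)`: delta `[1,5)`, theta `[5,9)`, alpha
`[9,15)`, beta `[15,31)`, gamma `[31,60)`.

Within a 5 s window the mean and median of a metric need a within-window
sample to average over; the package computes metrics per 1 s sub-epoch
and takes the mean/median across the five sub-epochs. This is a declared
interpretation — a window-level distribution has to come from somewhere,
and 1 s sub-epochs give five nearly independent spectral estimates at a
1 Hz resolution that still separates the bands.

Line interference is removed by a zero-phase second-order IIR notch at
50 Hz. The −3 dB bandwidth defaults to 2 Hz: wide enough that the filter's
transient decays within about a second of signal (a 1 Hz notch at Q = 50
rings for several seconds and leaks measurable power into steady-state
estimates), narrow enough to leave the gamma band essentially untouched
(<0.001 dB at 10 Hz in the test suite's measurement). Amplitude artifacts
are flagged where |v| exceeds 200 µV on any channel, and the flag is
dilated to the containing non-overlapping 5 s epoch; flagged epochs never
enter feature extraction.

## The synthetic cohort generator

No public recordings accompany the study design this package implements,
so the generator is a first-class module rather than a fixture: every
downstream stage is exercised against cohorts whose ground truth is known.

Each channel is a sum of per-band sinusoids at band-centre frequencies
(random phase per channel), 1/f-shaped background noise, a 50 Hz line
component and occasional half-sine artifact pulses (200–500 ms, peak
250–400 µV — deliberately above the 200 µV rejection rule). Artifact
counts are Poisson in the configured rate. Placing tones at band centres
keeps the analytic bookkeeping exact: a tone of amplitude A carries power
A²/2, so expected ratio metrics are exact functions of the configured
amplitudes, which the calibration tests exploit.

**Calibration.** The five reported per-region group means of the ratio
metrics are mutually inconsistent as functions of a single
(theta, alpha, beta) power triple: for the frontal high-SA row, α/β =
0.457 but (α+θ)/β · (1 − θ/(α+θ)) = 0.833 × 0.747 = 0.622 ≠ 0.457. A
power-based generator has two free ratios per region, so it can pin
exactly two metrics. `calibrate_band_amplitudes()` anchors on the
(θ/β, α/β) pair — which also pins (α+θ)/β exactly, since
(α+θ)/β = θ/β + α/β holds both in the table and algebraically — and lets
θ/(α+θ) and (α+θ)/(α+β) fall where the algebra puts them.

**Between-subject variability.** Subjects draw log-normal multipliers on
each band power (SD 0.15 on the log scale), shared across regions with a
small region-specific jitter (SD 0.05). Sharing across regions reflects
that a subject's band power is a stable individual trait, and makes
same-metric comparisons in different regions strongly dependent — as they
would be in real data. SD 0.15 places the weakest planted frontal/central
contrast near Cohen's d = 2, the effect size at which the package's power
checks are benchmarked.

**What the generator does not emulate:** physiological artifact
morphology (ocular/cardiac templates), non-stationarity within a
recording, volume-conduction correlation between neighbouring channels,
and reactive band-power dynamics. Passing tests therefore demonstrate
correct and calibrated computation, not field performance on real EEG.

## Permutation screening

Epochs within a subject are strongly dependent, so the permutation unit
is the subject: one mean metric value per subject per (metric, region),
13 high-SA vs 12 low-SA by default. The two-sided p-value uses the
additive-one correction `p = (1 + #{|t*| ≥ |t_obs|}) / (n_perm + 1)`
(10,000 permutations by default; the Monte-Carlo grid then resolves the
0.05 and 0.1 tiers comfortably). Two significance tiers are reported —
`a` for p < 0.05 and `b` for p < 0.1 — and selection uses the lenient 0.1
tier over regions F and C, so borderline frontal effects (the α/β kind of
case, p ≈ 0.07) are retained. Significant parietal/occipital pairs are
reported but never selected.

The printed Welch statistics of the study's comparison table are not
reproducible from its own printed means, SDs and group sizes (the frontal
(α+θ)/β row gives ≈9.8, not 2.151), so the package treats that table's
t/p values only as a significance pattern and as enumeration inputs,
never as numeric targets.

## Random-forest reduction

OOB noise-injection importance follows the difference-of-errors reading:
for each feature, its values are permuted (the standard implementation of
"adding noise" — no noise distribution is specified by the method's
source), every tree is re-scored on its own out-of-bag rows, and the
importance is `Σ_trees(errOOB2 − errOOB1) / Ntree`, with trees lacking
OOB rows skipped and `Ntree` adjusted. The forests themselves are
`ranger` fits (the grid search defaults to ensembles of 1–50 trees and
depths 1–20 under 5-fold cross-validation); the importance statistic is
computed by this package from per-tree predictions because no installed
implementation exposes that exact quantity.

Elimination is scored by the nonstandard normalised RMSE
`sqrt( Σ(y_obs − y_pred)² / Σ(y_obs − ȳ_pred)² )` with `ȳ_pred` the mean
prediction — implemented verbatim, denominator and all, as
`paper_rmse()`; a textbook `conventional_rmse()` is provided for
reference but does not drive elimination. The accompanying relative error
RE is defined here as mean absolute error over the observed label range
(an interpretation; the quantity is named but never defined at source).
Predictions are cross-validated class probabilities. Each round drops the
single lowest-importance feature (ties broken by dropping the
lexicographically last name, with a logged message), so p features yield
a p−1-entry trace, and the retained set is the RMSE minimiser. Rank, not
name, decides eliminations: the source's importance table contains a
duplicated name, so names are not a reliable key. Cross-validation folds
are epoch-level by default (the protocol the source describes); a
subject-level `groups` argument avoids within-subject leakage when that
is preferred.

## PCA combination

Features are z-scored before PCA — the ratio metrics live on
heterogeneous scales, and the unit-norm loading constraint presumes a
correlation-matrix analysis. Components are ordered by decreasing
eigenvalue, and each loading row's largest-magnitude entry is made
positive so orientations are reproducible. Selection keeps the smallest k
whose cumulative contribution reaches the threshold (87.7% by default);
a fixed `k` wins when both are supplied. The published eigenvalue column
for this step is internally inconsistent (it is unsorted and does not
match its own contribution column under any total), but the
contribution → cumulative → composite-weight chain is arithmetically
consistent, and that chain is what the package reproduces: the six
printed composite coefficients follow from
`w_k = contribution_k / 87.705` to four decimals.

Component scores of `stack` consecutive same-subject epochs (20 by
default, stride configurable) form the columns of a 13 × 20 input map,
zero-padded below the k component rows and min-max scaled per component.
How a k-component vector becomes a 13 × 20 map is nowhere specified at
source; epoch stacking is this package's declared construction — it
preserves short-term temporal structure across the map's width, which is
what a convolution along columns can exploit.

## The PCA-fused CNN

Two convolution blocks (5 × 5 valid kernels, ReLU), each followed by
3 × 3 max pooling and a fusion step, then a fully connected softmax head
with two units and cross-entropy loss. Pooling uses stride 1 with
same-padding: 13 × 20 inputs leave little spatial extent, and stride-1
pooling preserves the map shape so the fusion addition is well defined
point by point.

Fusion implements "reduce the convolution output, then add it to the
pooled map point by point": flatten the activated convolution map,
project it onto the top-m principal subspace (m = 8 by default) of
warm-up convolution activations — mean µ and loadings V fitted once on up
to 64 training maps and frozen — and add the reconstruction
`V Vᵀ (x − µ)` to the pooled map. With a zero (or absent) basis the fused
network reduces to the plain CNN *exactly*, which the tests assert
bit-for-bit; this ablation identity is also how the plain-CNN comparator
is built.

Training is plain SGD (no momentum — none is specified at source) with
learning rate 0.1, weight decay 10⁻⁴ applied to weights but not biases,
mini-batches of 20, and the stated adaptation rule: if the epoch-mean
loss rises by more than 25% over the previous epoch, the learning rate is
halved. "Iterations" count mini-batches; an epoch is
`floor(n_train / batch)` iterations. The 75%/25% train/test split is
stratified at the sample (epoch-stack) level by default, matching the
protocol of randomly selected feature samples; `split_by = "subject"` is
available when subject-level generalisation is the question. Backprop is
hand-derived and verified against central finite differences to better
than 10⁻⁴ relative error (in practice ~10⁻⁹); the check nudges biases
off zero because exact ReLU kinks — where subgradient and finite
difference legitimately disagree — otherwise occur at dead zero patches.

## Evaluation

TP/FP/TN/FN use the standard definitions (the narrative definitions in
the source of Eqs for TN/FN are internally garbled — they would make TN a
mislabelled positive — so the textbook convention is used and documented
here). MCC, F1 and kappa use their textbook formulas. Ratios with zero
denominators are reported as `NaN`, never silently zero. AUC is the
rank-statistic form (probability a positive outranks a negative, ties
half) and equals an exhaustive pairwise count exactly; the ROC curve
sweeps all thresholds. `compare_methods()` trains the three classifiers
on identical splits over repeated derived seeds and reports per-repeat
distributions plus a mean table; whether repetition means fresh splits or
fresh training runs is configurable because the source leaves it open.

## Why exact feature recovery is structurally bounded

One acceptance experiment asks the screening stage to recover *exactly*
the planted pairs {α/β, θ/(α+θ), (α+θ)/β} × {F, C} in at least 9 of 10
seeded cohorts, on cohorts where *only* those differ. Two facts make
that bar unreachable for any exact level-0.1 test on this generator:

* **The confound is algebraic, not statistical.** All five metrics are
  functions of one (θ, α, β) triple per region — two free ratios. Forcing
  α/β to differ while holding both θ/β and (α+θ)/(α+β) equal across
  groups forces α/β equal (solve (α/β + θ/β)/(α/β + 1) = const with θ/β
  fixed), a contradiction. The cleanest attainable design holds θ/β equal,
  which leaves a residual (α+θ)/(α+β) difference of ≈0.12 on the log
  scale — about d ≈ 1 at the calibrated noise level, detected at the 0.1
  level more often than not. Shrinking the noise to suppress it
  *increases* its detectability; growing the noise destroys power on the
  planted pairs (the d ratio ≈ 0.6 between confound and weakest planted
  contrast is fixed by the table's own values).
* **The false-positive floor.** θ/β is genuinely null in this design, and
  an exact permutation test rejects it at rate 0.1 at the selection
  threshold. Even with the two regions perfectly correlated this caps the
  per-seed probability of an exactly-correct selection at 0.9, so 9/10
  exact recoveries cannot be a reliable outcome even before the confound.

The package therefore reports the exact-recovery rate honestly (the
acceptance script's `selection_exact_recovery_rate`; observed values sit
near 0–1 out of 10, with the composite ratio or a θ/β false positive
joining the selection in most seeds) and the corresponding acceptance
assertion documents the shortfall rather than weakening the test. The
end-to-end criteria that are attainable — hybrid classifier AUC ≥ 0.9 on
the calibrated cohort and a chance-level label-shuffled control — pass
comfortably.

## Problem sizes and numerical choices

The test suite and acceptance script size their simulations for a
single-CPU run: 60 s recordings for screening cohorts and 180 s for the
end-to-end classifier run (25 subjects, 13 + 12), 1,999 permutations per
screening comparison (10,000 remains the analysis default), 600 training
iterations for the hybrid classifier and 300 for shuffled controls, 500
null simulations for the type-I check and 200 for power. Calibration
checks use noiseless 10-minute recordings where tone algebra is exact.
Other numerical choices collected in one place: additive-one permutation
p-values; half-open contiguous bands; DC excluded from band powers;
elimination ties dropped by lexicographically last name; PCA sign fixed
by the largest loading entry; fusion bases frozen after warm-up;
`NaN` (never 0) for undefined evaluation ratios; seeds derived by
integer mixing so every stage has an independent, reproducible stream
below 2³¹.

## Known limitations

* The generator's stationary tones make within-subject epochs far more
  homogeneous than real EEG; epoch-level splits therefore flatter any
  classifier. Use `split_by = "subject"` for a leakage-free read.
* The fusion operator, input-map construction, within-window statistic
  and RE definition are declared interpretations of an underspecified
  source; each is isolated behind its own function so alternatives can be
  swapped in.
* No EDF I/O: recordings interchange as a plain CSV dialect
  (`label@region` headers) and generator specs as YAML.
* The CNN is a compact CPU implementation for 13 × 20 maps, not a
  general-purpose deep-learning stack.
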