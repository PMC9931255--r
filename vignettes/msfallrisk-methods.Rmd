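---
title: "Free-living gait analysis and fall-risk classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-living gait analysis and fall-risk classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Persons with multiple sclerosis (PwMS) fall often, and fall risk fluctuates
faster than biannual clinic visits can observe. Continuous monitoring with a
chest and a right-thigh accelerometer (tri-axial, 31.25 Hz, worn for about two
days of daily life) offers a way to estimate fall risk from walking as it
actually happens at home. `msfallrisk` implements the full analysis chain for
such data — window-level activity classification, walking-bout assembly,
stride event detection, per-bout gait parameters, duration-stratified group
statistics, and leave-one-subject-out (LOSO) fall-risk classification — plus
a synthetic dual-sensor generator with complete ground truth so that every
stage is verifiable without any recorded data.

The emulated study conditions are a cohort of 38 PwMS, 21 self-reported
fallers and 17 non-fallers, each wearing the two sensors at home; free-living
walking is dominated by short bouts (roughly 61% short, 32% medium, 7% long by
count), and fallers differ from non-fallers in specific gait parameters —
notably a lower chest anterior-posterior (AP) acceleration RMS in short bouts
and a slightly lower duty factor in long bouts.

## Pipeline stages and their assumptions

**Windows and bouts.** Recordings are tiled into non-overlapping 4-s windows
(trailing remainder dropped). Windows are labelled gait/non-gait either by a
trained recurrent classifier (a single bidirectional LSTM layer, full-scale
default 215 hidden units with 40% dropout, Adam optimizer) or by a
deterministic spectral detector that thresholds the 0.4–3 Hz band power of the
mean-removed thigh AP channel (default threshold 0.02 g²; the walking/rest
power contrast in both synthetic and typical real data is more than an order
of magnitude). Maximal runs of gait windows become walking bouts, so a single
non-gait window separates bouts and every bout duration is a multiple of 4 s.
Non-overlapping windows are the simplest reading of fixed-length segment
classification and make the duration classes below exact.

**Cadence and stride events.** Within each bout, stride frequency is the
dominant peak of the Welch power spectral density (10-s Hann segments, 50%
overlap, or the whole bout when shorter) of the mean-removed thigh AP channel
in 0.4–1.2 Hz; step frequency is the dominant peak within ±20% of twice the
stride frequency. A bout whose peak is below 10× the median broadband
(0.3–5 Hz) power is flagged `cadence_not_found` and removed. A zero-phase
filter bank (4th-order Butterworth, two pole pairs, forward–backward) centred
at the stride and step frequencies with ±20% relative bandwidth provides a
stride-band signal whose peaks gate the signal into one cycle per stride.
Event *localization* deliberately does not use the narrow step band: a signal
band-limited to ±20% around twice the stride frequency is an almost-pure
sinusoid whose extrema are pinned to quarter-stride spacing, so it cannot
carry the phase of a foot off at ~62% of the stride, nor localize an impact to
a couple of samples. Instead, foot contacts are the apex of a wide
transient-band signal (2.5–10 Hz, zero-phase) within each gated cycle — the
band where heel-strike impact energy concentrates — and the foot off is the
subsequent transient-band trough before the next contact. Ties break to the
earliest sample, and contacts closer than half a stride period are pruned
(stronger peak wins). Strides are assembled from consecutive contacts, so
stance + swing = stride holds exactly by construction.

**Validity filtering.** Bouts with fewer than two strides are removed;
individual strides with stride time outside 0.5–3 s, duty factor outside
0.45–0.85, or stance/swing below 0.1 s are deleted, and the two-stride minimum
is re-checked. These ranges are the package's operationalization of
"physiologically impossible"; every filter step logs
(n_before, n_removed, n_after) and the identity n_before − n_removed = n_after
is enforced by construction.

**Gait parameters.** Eight features are computed for every bout: means of
stride, stance and swing time; coefficients of variation (sample SD with n−1,
divided by the mean) of stride time and duty factor; mean duty factor; RMS of
the mean-removed chest AP channel (reported in g — a sensor-data unit, not a
square root of one); and the medial-lateral frequency dispersion, defined here
as the PSD-weighted standard deviation of frequency over (0, fs/2] of the
mean-removed chest ML channel — a spectral-spread quantity in Hz, invariant to
amplitude. Long bouts (≥ 32 s) add the thigh/chest sample-entropy ratio
(m = 2, tolerance r = 0.2×SD of each series, computed on the mean-removed
vector-magnitude acceleration; the axis is a package choice since resultant
acceleration is orientation-robust). Laboratory one-minute bouts add the
largest Lyapunov exponents of the chest AP and ML channels, estimated by the
divergence-curve method: delay embedding in dimension 5 with the delay at the
first autocorrelation minimum capped at a quarter stride period, nearest
neighbours outside a one-stride Theiler window, mean log divergence over 0–0.5
stride periods, slope by least squares, in 1/s. Lyapunov exponents are
restricted to the lab feature set (arity 8/9/11 for short–medium–all/long/lab)
even though any bout over 60 s could support them; `lyapunov_home = TRUE`
computes them on long home bouts for exploration.

**Duration classes and statistics.** Bouts are short (≤ 8 s), medium
(12–28 s) or long (≥ 32 s); the 4-s quantization makes this total. Subject
summaries use seven statistics (mean, median, max, min, SD, 5th and 95th
percentile) with percentiles by linear interpolation between order statistics
(quantile type 7) — stated explicitly because percentile conventions differ
across software. Group comparisons are two-sided Wilcoxon rank-sum tests at
α = 0.05 with *no* multiplicity correction (a Benjamini–Hochberg option
exists, off by default): exact enumeration when the smaller sample has ≤ 8
observations and there are no ties, tie-corrected normal approximation
otherwise. Duration-vs-duration and lab-vs-home comparisons pool bout-level
values; faller-vs-non-faller comparisons use per-subject summary statistics,
because summary-level contrasts (e.g. "median RMS AP") are the quantities of
interest at the subject level; both units are selectable via `unit=` since
the choice is genuinely open.

**Fall-risk classification.** Feature-based: per LOSO fold, z-scoring and PCA
are fitted on training rows only and the smallest number of components
reaching ≥ 95% cumulative variance is kept (a mutation test verifies held-out
rows never influence the transform); five families (logistic regression, RBF
SVM, decision tree, k-NN, random-forest ensemble) are tuned by seeded random
search inside the training subjects (inner holdout of ~25% of training
subjects). Pooled held-out scores give a per-input AUC; per-subject median
scores give the aggregated AUC; AUC is the Mann–Whitney pair statistic with
ties counted ½. Sequence-based: inputs are 6 channels of raw acceleration
(chest + thigh) over k consecutive strides, built by a step-1 sliding window
over each bout's stride sequence ("every consecutive k strides"; the
disjoint-block alternative is selectable) — the sliding window maximizes
training data, which recurrent models need. The subject's balance-confidence
(ABC) score can be appended as a constant extra channel, z-scored with the
other channels on training statistics. The modified LOSO holds out one test
subject and one validation subject chosen by fixed rotation (next subject id,
cyclically — a deterministic choice the package makes where any disjoint
assignment would do), trains on the rest, and aggregates per-subject medians.
The positive class is "faller" throughout.

**The recurrent engine.** Both the window classifier and the sequence models
run on a compact LSTM/BiLSTM engine written in R: stacked (bi)directional
LSTM layers over padded variable-length sequences with a validity mask
(padded steps carry state through and never influence the masked temporal
mean pooling), inverted dropout, a dense softmax head, cross-entropy loss and
Adam. Gradients are verified against finite differences in the test suite,
and training is exactly reproducible under a fixed seed. Two full-scale
architectures are predefined — `arch_lstm2()` (LSTM-290/30% + BiLSTM-10/40%,
55 epochs) and `arch_lstm3()` (LSTM-85/55% ×2 + LSTM-235/45%, 125 epochs) —
while tests and the acceptance script use reduced specs (e.g. 8 hidden
units, 8 epochs), which exercise the identical code path.

## The synthetic generator

The generator is first-class, tested code, and its defaults define the
conditions everything else is validated under.

Per-subject profiles draw gait parameters from truncated normals anchored at
free-living medians for moderately impaired PwMS: stride time 1.16 s (SD
0.08), stride-time CV 0.067, duty factor 0.62, chest AP RMS 0.145 g, ML
spectral width 0.62 Hz. Survey scores (ABC, EDSS, MFIS, MSWS, NSI) come from
group-specific normals matching the emulated cohort's demographics, clipped
to instrument ranges. Faller effects are multiplicative on named parameters;
the defaults lower RMS AP by the factor 0.13/0.15 ≈ 0.87 and duty factor by
0.61/0.63. The between-subject SD of AP amplitude (0.024 g) is calibrated so
that this contrast at 21 vs 17 subjects reproduces a rank-sum significance
level near p = 0.02 — i.e. a standardized group difference of about 0.85 —
which ties the generator's noise level to the observable the cohort is known
by rather than to an arbitrary choice.

Each walking segment draws per-stride durations from a truncated normal with
the profile's mean and CV, snapped to the sample grid so returned events are
exact ground truth (zero CV therefore yields bit-identical strides). The
thigh AP channel carries a stride-frequency harmonic, a sharp positive
Gaussian impact transient (σ = 30 ms) at each foot contact and a negative
transient (σ = 40 ms) at each foot off, placed at duty × stride after the
contact. The chest AP channel is the profile's AP amplitude times a
fixed-shape unit-RMS waveform, so chest AP RMS scales exactly linearly with
the profile parameter. Axis order is fixed as [vertical, ML, AP] and gravity
appears as +1 g on the vertical channel; downstream features remove per-bout
means, so this convention is load-bearing only for readability.

Recordings interleave bouts with non-gait filler — band-limited Gaussian
noise at ~10% of walking amplitude plus sparse posture-shift ramps — drawn
from a short/medium/long mixture (defaults 0.61/0.32/0.07) with durations
uniform on {4,8}, {12,…,28} and {32,…,120} s in 4-s steps. The filler's
spectral shape is a stand-in: real non-gait activity is far richer
(transport, fidgeting, cycling), so a high window-classification accuracy on
synthetic data demonstrates the training/inference machinery, not expected
accuracy on real recordings. Similarly, the generator produces no turns,
stairs, assistive-device gait or bilateral asymmetry, so event-detection
accuracy here bounds performance only for steady straight-line walking.

`simulate_bout_parameters()` is a deliberate statistical shortcut for
calibration studies: it draws per-bout parameter tables directly from
profiles with within-subject noise, giving the same object the full signal
path produces at a small fraction of the cost. Power and null-calibration
studies use it; signal-path correctness is established separately by the
event-recovery and feature-recovery tests.

## Numerical choices and degenerate inputs

- All randomness flows through seeds; derived child seeds stay below 2³¹.
- Welch PSD: Hann window, mean removal per segment, one-sided scaling.
- Filter edges are validated against (0, fs/2); zero-phase filtering keeps
  pulse apexes in place, which the event localizer relies on.
- Identical samples in both Wilcoxon groups short-circuit to p = 1.
- A single bout yields SD 0 in subject summaries (not NA).
- Sample entropy returns `Inf` when no (m+1)-matches exist; the entropy ratio
  errors on zero chest entropy.
- The Lyapunov estimator skips exactly coincident embedded states; a
  noiseless periodic signal therefore reports a slope near 0 rather than
  −∞.
- LOSO under a permutation null is slightly pessimistic (below 0.5): with one
  subject held out, the training class balance anti-correlates with the
  held-out label. This is a property of LOSO itself, visible in the
  calibration numbers, not a defect of the models.

## Problem sizes

The test suite and acceptance script run reduced problem sizes chosen as the
smallest that still demonstrate each property: stride-event recovery on 25
strides per speed across 0.8–1.8 s stride times; window-classifier training
on ~0.4 h of synthetic wear time with an 8-unit BiLSTM; Wilcoxon calibration
on 200 null replicates and 100 effect replicates at the 21:17 split;
permutation-null LOSO over 20 seeds at 40 subjects; sequence models with 8
hidden units and 8 epochs on 8-subject cohorts. The full-scale architectures
and multi-hour, 38-subject simulations run through the same interfaces when
more compute is available.

## Known limitations

- No gait speed, step length or any distance-calibrated metric: two
  accelerometers cannot observe them without additional assumptions.
- Binary gait/non-gait classification only; running, stairs and transitions
  are out of scope.
- No bilateral (left/right) event attribution from the single right-thigh
  sensor.
- The generator's group effects are multiplicative shifts; real faller gait
  differs in richer ways (variability structure, asymmetry, fatigue drift),
  so classifier AUCs on synthetic cohorts characterize the pipeline, not
  expected clinical performance.
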