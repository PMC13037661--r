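---
title: "Decoding finger movements from source-space MEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding finger movements from source-space MEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fingermeg)
```

## The problem

Individual finger movements are represented only millimeters apart on the
contralateral primary sensorimotor cortex, which makes them hard to separate
with non-invasive recordings. MEG offers millisecond temporal resolution and
enough spatial resolution, after source reconstruction, to attempt
single-trial four-class decoding of thumb, index, middle and little finger
extensions. `fingermeg` implements the full analysis chain — EMG-defined
movement onsets, band-limited epochs, LCMV beamforming, activation-index
mapping, time-resolved multivariate decoding, virtual-channel window
combination, voting-based digit maps, and the accompanying nonparametric
statistics — together with a forward-model simulator that generates sensor
epochs and EMG traces with full ground truth, so every stage is testable
without human recordings (which are not distributable for studies of this
kind).

## EMG processing

Raw EMG is band-pass filtered 20–450 Hz, full-wave rectified, and smoothed
with a 50 Hz low-pass; all filters are 4th-order Butterworth run
forward–backward so the envelope has no group delay. The per-trial movement
threshold is

$$T = \mu + k\,\sigma, \qquad k = 2,$$

with $\mu$ and $\sigma$ the mean and (n−1) standard deviation of the
envelope over the epoch. The first sample strictly above $T$ is the
movement onset; the last sample of the last supra-threshold run is the
offset. Reaction time is onset minus cue; movement time is offset minus
onset. Two conventions here were genuinely open and are settable:

* whether the threshold statistics use the full epoch (default, as the rule
  is written) or a pre-cue baseline window (`stat_window`);
* the offset is the last supra-threshold sample — "the last time point at
  which the signal dropped below the threshold" read as the end of the
  final burst.

Ties at exactly $T$ do not trigger an onset (strict inequality).

## Sensor preprocessing

Epochs span $[-2, 2)$ s around the EMG-defined onset at 300 Hz (1200
samples; the half-open grid makes the 50-ms window tiling of $[-1, 2)$
exactly 60 windows of 15 samples with no shared boundary samples). Six
bands are used throughout: δ 0.5–4, θ 4–8, α 8–13, β 13–30, γ 30–60,
high-γ 60–90 Hz. Band-passes are realised as a high-pass/low-pass cascade
of 4th-order Butterworth stages applied forward–backward with odd edge
extension; the cascade is far better conditioned than a single 8th-order
transfer function at edges like 0.5 Hz on a 300 Hz grid. Resampling
decimates after a zero-phase anti-alias low-pass at 0.8 of the target
Nyquist.

## Source reconstruction and activation index

The beamformer is the unit-gain LCMV spatial filter. With data covariance
$C$ (pooled over all trials and samples, Tikhonov-regularized by
`reg * mean(diag(C))` on the diagonal, default `reg = 0.05` — the
conventional default; the source is silent on the value), the weight row
for a vertex with lead field $l$ is $w = C^{-1} l / (l^\top C^{-1} l)$.
Source orientation is estimated per vertex as the direction of maximal
reconstructed variance: for unit-gain filters the output variance along a
tangential direction $u$ is $1/(u^\top S u)$ with
$S = L^\top C^{-1} L$ restricted to the tangential plane, so the chosen
orientation is the eigenvector of $S$ with the smallest eigenvalue. Radial
directions are excluded a priori because they are externally silent in the
spherical head model.

Spatial task maps use the activation index at each vertex $i$ and trial:

$$A = \frac{w C_s w^\top - w C_b w^\top}{w C_s w^\top + w C_b w^\top},$$

with $C_s$, $C_b$ the trial's channel covariances over the task and
baseline windows (baseline $[-2, -1.5)$ s; task $[-1, 2)$ s, or one 50-ms
window for the windowed maps). $A$ is computed per trial and averaged
within task. Two numerical conventions the source leaves open:

* per-window covariances use the biased $1/n$ normalizer — with 15-sample
  windows the $(n-1)$ distinction is material and $1/n$ keeps the quadratic
  forms consistent with nonnegative-definite covariances;
* window means are removed by default (`demean = TRUE`); raw second moments
  are available.

$A = 0$ exactly when task and baseline covariances agree, the index is
antisymmetric under swapping the windows, and it lies strictly inside
$(-1, 1)$ whenever both quadratic forms are positive; a zero denominator
yields NaN with a warning. Extrema ties break toward the lowest vertex
index.

Beamformer weights are fitted once on all trials while activation maps and
extrema are recomputed from the training trials of each cross-validation
fold — replicating the published leakage profile (reconstruction on all
trials, maps on the 80% training split). The fold-aware feature
constructors (`pca_feature_fun()`, `a_epoch_feature_fun()`,
`a_window_feature_fun()`) enforce that loadings and extrema never see test
trials.

## Time–frequency analysis

Morlet wavelets with 4 cycles (temporal SD $n_c/(2\pi f)$, unit-energy
kernels, FFT convolution). Samples within one wavelet half-width
($n_c/(2f)$) of an epoch edge are flagged invalid rather than masked to
NaN, since downstream arithmetic needs dense arrays. The evoked response is
the TFR of the trial-averaged signal; the induced response is defined as
total minus evoked on the same grid, so the identity
`evoked + induced = total` holds exactly by construction (induced power may
be negative pointwise; this is flagged in the documentation rather than
clipped). Task-versus-baseline maps are paired t statistics per
(frequency, time) cell, with significance left to the cluster permutation
test.

## Decoding

All classifiers are linear one-versus-rest SVMs (binary LIBSVM fits via
e1071, C = 1 by default; the source names no value) under stratified
5-fold cross-validation with per-fold standardization fitted on training
data. e1071's built-in multiclass mode is one-versus-one, so the
one-versus-rest decomposition is constructed explicitly: one binary
machine per class, decisions by maximal decision value.

Five feature pipelines mirror the analysis design: point-wise (all-vertex
amplitudes at one sample), window-wise (per-trial vertex activation indices
of one 50-ms window), PCA-based (retained ROI components over the task
period, 70% cumulative variance), A-epoch-based (time series at the eight
full-epoch extrema vertices), and A-window-based (per-window extrema
segments concatenated over the 60 windows — dimensionality identical to the
A-epoch features by construction). Duplicate extrema across tasks are
retained so the stated dimensionality is preserved. A power-feature variant
(`features_power()`) substitutes Morlet power for raw time series.

Virtual channels collect the eight extrema of every window whose
window-wise accuracy is significantly above the 25% chance level
(cluster-based permutation across subjects at α = 0.05); the series are
downsampled to 30 Hz before segment extraction; single-window and
window-combined schemes are compared under identical folds.

## Statistics

Friedman tests (midranks, χ² reference), Wilcoxon signed-rank tests
(zero differences dropped, midranks; exact sign-flip distribution when
n ≤ 25 without ties, otherwise a tie-corrected normal approximation with
continuity correction; the signed z is always reported),
Benjamini–Hochberg step-up adjustment, cluster-based permutation tests
(per-point t, cluster-forming threshold at two-sided p < 0.05 with
subject df — one-sided for accuracy-versus-chance — cluster mass = summed
t, max-mass null over random sign flips, 5000 permutations by default,
p-values honoring the $1/(n_{perm}+1)$ lower bound), and one-sided
vertex-wise permutation tests with BH correction within each window for the
digit maps. The subject-level statistic fed to the cluster test is the t
statistic (the alternative was open; t is standard for accuracy-minus-chance
series). A caveat worth knowing: with $n$ subjects the sign-flip null has
$2^n$ atoms, so fewer than six subjects cannot reach p < 0.05 at all.

## Digit maps

Each vertex is decoded from its own 50-ms segments; per-vertex labels take
the class with the highest class-conditional recall, with exact ties left
unassigned (arbitrary tie-breaks would contaminate the group vote). Group
maps assign, within the mask of vertices significantly above chance, the
label held by the most subjects; voting ties stay unassigned. Per-finger
vertex counts are thresholded at 25% of one-fourth of the maximum total
assigned count across windows.

## The synthetic data generator

The generator is a first-class module: it defines the study conditions
under which every property above is tested.

**Geometry.** 200 ROI vertices on a spherical-cap patch (8 cm shell,
0.35 rad angular radius, tilted toward the left hemisphere as a stand-in
for the contralateral sensorimotor hand region) inside 64 radial
magnetometers on a 12 cm Fibonacci hemisphere. The lead field is the
closed-form field of a current dipole in a homogeneous conducting sphere,
for which radial moments are silent; orientations are tangential. The
orientation field is spatially smooth — a common patch direction plus
per-vertex jitter — mirroring the locally coherent surface normals of a
cortical patch. This matters: with fully random orientations, the summed
field of adjacent coherent sources is not explained by any single dipole
at the cluster and localization is biased by centimeters.

**Signals.** Per trial, the active finger's vertex carries a phase-locked
δ bump (Gaussian envelope, SD 0.35 s, 2.5 Hz, peak at onset, latency
jitter ≤ 50 ms, fixed polarity) and a θ bump (SD 0.2 s, 6 Hz), plus a weak
random-phase high-γ burst at onset; a shared set of vertices carries α
(10 Hz) and β (20 Hz) oscillations with random phase per trial whose
envelope dips before/during movement (ERD) and rebounds afterwards (ERS);
all vertices carry 1/f background. Sensor noise is white, scaled to a
target signal-to-noise variance ratio (default 1). Defaults:
40 trials per task, 300 Hz, epochs $[-2, 2)$ s.

Task-specific activity defaults to one focal vertex per finger with a
patch-equivalent moment (`amp_delta = 3`) rather than a multi-vertex
coherent cluster. The reason is a genuine property of LCMV: coherent
correlated sources partially cancel one another, so a tight coherent
cluster is reconstructed *weaker* at its own vertices and its activation
maximum can displace by many millimeters. `cluster_size` remains a knob for
studying exactly that failure mode. Per-finger source separation is
likewise a knob (`active_vertices`), not an asserted value — the spatial
separation of finger representations is not something the generator should
hard-code.

**EMG.** Epochs of 4 s at 1000 Hz with the cue at 0.5 s; reaction times
are Gaussian with mean 642.65 ms and SD 89.74 ms, and per-task burst
durations center on 241.18, 252.72, 288.60 and 294.50 ms — the group-level
conditions the analysis expects for isolated extensions of the four
fingers; the trial-level duration SD (60 ms) is this package's choice.
Bursts are envelope-modulated white noise (fast rise/fall, task-specific
amplitude and decay shape, so the four classes are learnable) preceded by a
brief *deterministic* synchronized compound potential (3× burst amplitude,
80 Hz, 6 ms ramp, 25 ms decay) emulating the initial agonist burst of
ballistic extensions. That synchronized onset is what makes threshold
crossings sharp in real brisk movements; with purely stochastic envelopes
the crossing time jitters by ~2 ms SD and onset recovery degrades
noticeably.

**What the generator does not emulate** — and hence what green tests do
not certify about real data: realistic head anatomy and BEM forward
fields, spatially correlated sensor noise, ocular/cardiac artifacts, head
movement, coherent extended patches (see above), inter-subject anatomical
variability beyond jittered source placement, and EMG cross-talk between
fingers.

## Problem sizes in the shipped tests

The test-suite and the acceptance script run the same pipeline at desk
scale, chosen so the whole suite completes comfortably on one core:
localization and recovery checks at 200 vertices / 64 channels; feature
pipeline comparisons at 60 vertices / 32 channels with 20 trials per task
over several generator seeds; chance calibration at 400 trials on a
16-channel model; digit maps with six simulated subjects (independent
generator seeds with source positions alternating between a canonical
center and its nearest neighbor) at 40 vertices. Statistical calibration
uses 200 replicates of 500-permutation cluster tests. Six simulated
subjects is also the minimum at which sign-flip permutation tests can reach
p < 0.05.

## Known limitations

* The spherical forward model and focal sources make localization easier
  than cortical reality; recovery rates here are upper bounds.
* Coherent extended sources violate the LCMV uncorrelated-source
  assumption; the generator's defaults sidestep this deliberately.
* The evoked/induced split attributes any trial-average leakage of
  non-phase-locked activity to the evoked compartment, as the subtraction
  definition dictates.
* The published leakage profile (beamformer weights fitted on all trials)
  is replicated by default; the strictly fold-separated path is available
  and used by the fold-aware feature constructors.
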