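---
title: "Decoding naturalistic behavioral states from ECoG band power: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding naturalistic behavioral states from ECoG band power: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecogstate)
```

## The problem

Long-term intracranial (ECoG) recordings from hospital monitoring units come
with only coarse behavioral annotation: video is split into 2-minute blocks
and each block is labeled with a state such as *Talking*, *WatchingTV* or
*UsingElectronics*. The scientific questions this package addresses are
(i) whether band-power features of the neural signal discriminate such
states, (ii) which (cortical region, frequency band) combinations carry the
discriminative signal and whether their direction is consistent across folds
and participants, and (iii) whether combining regions adds information.

The pipeline is: preprocess the raw voltages, extract Hilbert-envelope band
power in five canonical bands, average into 10-s bins, map electrodes to
regions of interest (ROIs) by Gaussian proximity, and classify state pairs
with a shared-covariance linear discriminant analysis (LDA) under a
temporally buffered cross-validation scheme, followed by group-level
inference with finite-sample chance levels and Benjamini–Hochberg FDR
control.

## Signal model and preprocessing

A recording is a channels × samples voltage matrix in microvolts. The
cleaning chain is fixed in this order:

1. **DC removal** — subtract the per-channel median.
2. **Bandpass 1–200 Hz** (order-4 Butterworth) and **notch filters** at the
   line frequency and its harmonics below Nyquist (biquads with Q = 30).
3. **Downsample** to 500 Hz (integer decimation behind a zero-phase
   anti-alias lowpass).
4. **Common-median reference** — subtract, at each sample, the median across
   good channels.

All filters are applied forward–backward (zero phase) by default. The choice
matters here: causal IIR filters delay different bands by different amounts,
which would misalign the 10-s feature bins across bands; zero-phase
application avoids that at the cost of acausality, which is irrelevant for
offline analysis. Recordings are treated as contiguous; data with gaps
should be processed per segment before feature extraction.

## Features

Five bands are used: theta (4–8 Hz), alpha (8–12 Hz), beta (8–32 Hz), low
gamma (32–55 Hz), high gamma (70–110 Hz). The beta band deliberately
overlaps alpha; the definition is kept exactly as published for this family
of analyses rather than "fixed" to 12–32 Hz. Each band is isolated with an
order-4 zero-phase Butterworth filter and its envelope taken as the
magnitude of the analytic signal (FFT-based Hilbert transform, computed per
contiguous segment). Envelopes are averaged over 10-s bins; a trailing
partial bin is discarded, so a 2-minute block holds exactly 12 bins.

**Artifact rejection.** A 2-minute segment is discarded when at least 10% of
channels spend more than 2 s above 3× their whole-recording standard
deviation. Two readings of "more than 2 s" are supported: cumulative
supra-threshold time (default — stricter and simpler) or a single contiguous
run (`artifact_rule(contiguous = TRUE)`). The SD is computed per channel
over the whole recording on the broadband signal, the most natural reading
of "the standard deviation of the channel".

## Electrode-to-ROI mapping

Electrode *i* is related to ROI *j* through a 3-D isotropic Gaussian of
their distance, `exp(-d²/(2σ²))`, so an electrode exactly at a centroid
scores 1. The width σ (default 10 mm) and the closeness threshold (default
`exp(-2)`, i.e. about a 2σ radius) are not fixed by the analysis this
package reimplements and are exposed as configuration; both are recorded in
exported metadata. Each electrode is assigned to its argmax-weight ROI if
that weight clears the threshold (ties break to the earlier ROI in column
order, for determinism), and ROIs with fewer than 3 assigned electrodes are
discarded, iterating assignment and density pruning to a fixed point.

## Classification protocol

For one (ROI, band) the feature matrix is kept bins × assigned electrodes.
The cross-validation scheme orders bins in time, splits them into 7
contiguous folds, and inserts a one-fold buffer on **both** sides of the
test fold: training folds are those whose index differs from the test
fold's by more than 1, with no wraparound. The symmetric buffer is the
conservative reading of "a one-fold buffer between the training and test
sets"; it guards against slow state drift leaking across the split in
either temporal direction.

Within each fold:

- training and test sets are **class-balanced separately** by seeded
  downsampling to the minority count;
- the two sets are **z-scored independently** (per feature, sample-SD
  convention, n − 1) — this removes slow trends and per-fold offsets so the
  classifier sees only within-fold structure;
- a **shared-covariance LDA** is fitted: per-class means plus one pooled
  within-class covariance, ridge-regularized by `λ · mean(diag(Σ))` with
  λ = 1e-3 to guarantee invertibility on small ROI slices. Because the
  covariance is shared, the class-mean difference is the only learned
  discriminative parameter — which is what makes the consistency analysis
  below meaningful.

The per-fold **mean difference** is the fitted class-mean difference
(first class of the pair minus the second, z units) per electrode; its
average over the ROI's electrodes is the scalar consistency statistic. The
electrode-average was chosen because the group analysis needs one value per
(ROI, band); projecting onto the discriminant direction is a reasonable
alternative and can be derived from the per-electrode vectors returned with
every evaluation.

With 5 participants and 7 folds each feature accumulates 35
accuracy values and 35 mean differences.

## Group-level inference

**Finite chance.** A finite test set lets a random classifier exceed 1/2
easily, so accuracies are compared against the binomial threshold: the
smallest k/n with `P(Bin(n, 1/classes) ≤ k−1) ≥ 1 − α` (α = 0.05), with n
the median per-fold test size. The pooled fold accuracies are tested
against this threshold with a two-sided Student t-test, and the mean
differences against zero. Each family of 40 p-values receives
Benjamini–Hochberg step-up control at α = 0.01, implemented directly from
the step-up definition and cross-checked against `p.adjust`. A feature is
**jointly significant** when both tests survive *and* its mean accuracy
actually exceeds the chance threshold — the directional guard matters
because a two-sided test would otherwise also flag features sitting
significantly *below* the finite-chance threshold, which is where null
features sit (their accuracy is near 0.5, the threshold above it).

A two-way fixed-effects ANOVA with interaction (`accuracy ~ roi * band` on
fold-level accuracies pooled over participants) quantifies group-level ROI
and band effects. Participant identity is deliberately not modeled as a
random effect, matching the analysis being reimplemented; with effects
concentrated in one cell the interaction term is expected to be large in
planted-effect simulations and near null otherwise.

**Incremental-ROI additivity.** ROIs are ranked by accuracy on a validation
fold held out *inside* the training partition — the training fold most
distant from the buffered test fold, itself separated from the inner
training folds by the same buffer — and test accuracy is reported as
electrodes from the top-1, top-2, … ROIs are concatenated. The placement of
the validation fold is not dictated by the source analysis; the
most-distant-fold rule preserves the temporal-buffer logic inside the
training partition.

## The synthetic generator

Real annotated multi-day ECoG cannot ship with a package, so the generator
provides a ground-truth test surface. Each channel is

```
x(t) = Σ_bands m(t) · a_b · sin(2π f_b t + φ) + pink(t) + drift(t)
```

- `f_b` is the geometric mean of the band edges, snapped to the nearest
  multiple of `1/block_s` so every 2-minute block holds an integer number of
  cycles (the snap is at most 1/240 Hz and keeps block spectra leakage-free);
- `m(t)` is the planted effect multiplier of the channel's ROI, band and
  the current block's state (1 when unmapped) — the recoverable ground truth;
- `pink(t)` is 1/f background noise generated per block in the frequency
  domain from a seeded stream (one stream per recording, split per channel
  by channel index, so adding channels never reshuffles existing ones);
- `drift(t)` is a slow sinusoid (default 25 µV, 900-s period) that exercises
  the z-scoring and the temporal buffer.

Default conditions for simulation studies: 5 participants, 60 two-minute
blocks, three states with Markov persistence 0.6, eight ROIs × 3 electrodes
(24 channels), carrier amplitude 1.5 µV against 20 µV broadband noise. The
amplitude was set once so that a multiplier-1.5 planted effect decodes well
above chance but below ceiling (fold accuracies around 0.85–0.95), which is
the regime where the consistency statistics are informative; with
deterministic carriers the 10-s bin averaging suppresses envelope noise
strongly, and larger amplitudes saturate accuracy at 1.0, making
t-statistics degenerate.

What the generator does **not** emulate: realistic cortical geometry and
volume conduction, cross-channel correlation beyond the shared behavioral
state, heavy-tailed artifacts other than injected square bursts, and
amplitude dynamics within a block. Passing recovery tests therefore shows
the pipeline recovers effects of the modeled kind; it does not certify
performance on clinical recordings.

A consequence worth knowing about: the common-median reference couples
channels, so a strong planted effect leaks with opposite sign and roughly
1/n_channels magnitude into the other channels' envelopes. This is a real
property of median re-referencing, visible in the simulations as slightly
negative mean differences in unmapped ROIs; at the default conditions the
leak stays far below significance.

## Execution engines and numerical choices

Three equivalent execution paths exist:

- `engine = "filter"` — the reference chain: time-domain synthesis,
  zero-phase IIR filtering (C++ forward–backward passes with odd-reflection
  padding, checked against `signal::filtfilt`), full-rate FFT Hilbert
  envelopes.
- `engine = "spectral"` — per-block frequency-domain feature extraction on
  an explicit recording: the zero-phase Butterworth is applied as its
  squared-magnitude response and the analytic signal reconstructed at a
  reduced rate from the band's spectral support (bins with |H|² > 1e-4).
- `engine = "fused"` (default for synthetic studies) — generates the block
  spectra directly (carriers are single FFT bins; pink noise is defined in
  the frequency domain), applies the preprocessing response, inverse-FFTs
  once for the common-median reference and artifact rule, and subtracts the
  median signal's spectrum before band slicing. The slow drift term is
  omitted because the 1-Hz high-pass removes it identically.

Binned features from the three engines agree to well under 1% in the median
(a few per cent worst-case in the narrow low-frequency bands at block
edges); tests pin this down. Reduced-rate envelope reconstruction uses
5-smooth FFT lengths that are multiples of the bins-per-block count, capped
at 6144 samples per block; spectrum folding beyond the cap is exact
time-domain subsampling, so it adds only sampling variance to the bin mean,
never bias. Simulation studies in the test-suite run at 250 Hz sampling
(bands reach only 110 Hz, so the feature content is unchanged from the
500 Hz default) with the bandpass capped below the Nyquist frequency.

Degenerate inputs are handled without aborting a 40-feature sweep:
zero-variance features z-score to 0 with a warning, zero-variance channels
leave the artifact rule's denominator, a fold missing a class is skipped
with a message, and zero-variance t-tests return `NA` flagged degenerate.
Ties — in the ROI argmax and in the discriminant argmax — break to the
earlier index, documented and deterministic.

## Problem sizes used by the tests

Unit tests run on seconds-long recordings. The acceptance-style property
tests use the full reference conditions (5 × 60 × 120 s) simulated at
250 Hz with the fused engine: 20 seeded planted-effect runs for recovery,
20 matched null runs for calibration, three-participant averages for the
additivity contrasts. These sizes keep the complete suite within a
half-hour on one core while leaving every scientific parameter of the
protocol (block and bin duration, fold counts, band table, FDR levels) at
its reference value.

## Limitations

- The beta band overlap with alpha means a planted alpha effect also
  appears in beta; plant in theta, low or high gamma for clean
  single-feature ground truth.
- The ANOVA treats folds as independent replicates; temporally adjacent
  folds share slow structure, so its p-values are anti-conservative on
  strongly drifting data.
- ROI σ and the projection threshold are conventions, not estimates; real
  localizations should calibrate them against anatomy.
- The NWB/DANDI adapter for clinical recordings is out of scope here; the
  feature table and ROI assignment are the interchange points where real
  data would enter.
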