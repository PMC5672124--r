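---
title: "Decoding finger movements from deep-brain LFPs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding finger movements from deep-brain LFPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpdecode)
```

# The problem

Deep brain stimulation (DBS) macroelectrodes implanted in the subthalamic
nucleus (STN) or globus pallidus interna (GPi) record local field
potentials (LFPs) — the aggregate synaptic activity of a local neural
population. Around a voluntary movement these signals show reproducible
band-specific changes: beta-band (13–32 Hz) amplitude drops
(event-related desynchronization, ERD), gamma-band amplitude rises
(event-related synchronization, ERS), and a large delta transient marks
the event onset. `lfpdecode` implements an offline decoder that uses
these signatures to answer two questions per trial, in order: *did a
movement occur (versus rest)?* and, if so, *was it a left- or right-cued
movement?*

Because clinical recordings of this kind are not publicly deposited, the
package ships a synthetic session generator that reproduces the relevant
phenomenology with known ground truth, so every stage of the pipeline is
testable end to end.

# Pipeline overview

1. **Preprocessing** (per channel): zero-phase Chebyshev type-I low-pass
   at 90 Hz, zero-phase 50 Hz notch, resampling to 256 Hz.
2. **Band decomposition**: level-5 wavelet packet transform (WPT) with
   the discrete Meyer wavelet; 32 frequency-ordered terminal nodes of
   4 Hz each, grouped into seven bands (delta 0–4, theta 4–8, alpha
   8–12, low beta 13–20, high beta 20–32, low gamma 32–60, high gamma
   60–90 Hz).
3. **Features**: Hilbert envelope of each band over the whole recording;
   per trial, the mean envelope in five consecutive 100 ms windows —
   −150…+350 ms around the motor response for movement trials,
   −750…−250 ms before the stimulus for rest trials. With 2 channels ×
   7 bands × 5 windows this gives 70 features per trial.
4. **Classification**: two binary stages (movement vs rest, then left vs
   right), each decided by majority vote over three base neural networks
   — a feedforward backpropagation network (FBANN), a radial basis
   function network (RBFNN) and a probabilistic neural network (PNN) —
   with each base score thresholded at 0.5.
5. **Evaluation**: stratified 10-fold cross-validation with
   nearest-neighbor weighted bootstrap balancing of the training folds,
   and a metrics suite (accuracy, sensitivity, specificity, OER, FPR,
   FNR, precision, F-measure, g-means, desirability, MCC, closed-form
   AUC, balanced accuracy, Cohen's kappa with standard error).

# The synthetic session generator

Each channel is the sum of seven amplitude-modulated narrowband Gaussian
oscillations (band-pass-filtered white noise, one per band), a 1/f-type
colored background, 50 Hz line interference, and a 400 ms delta-band
burst at each event onset. Narrowband noise rather than sinusoids keeps
the envelope statistics realistic (Rayleigh-like single-trial
fluctuations), which is what makes the decoding problem nontrivial.

Movement events multiply the band envelopes by configurable gains with a
raised-cosine time course: a 200 ms ramp starting 150 ms before the
motor response, a 500 ms plateau, and a 200 ms recovery. A gain below 1
produces ERD, above 1 ERS. Laterality is encoded by applying the full
gain on the channel contralateral to the cued hand and a halved effect
(`1 + (g − 1)/2` with the default 2:1 contrast) ipsilaterally. The
contra/ipsi contrast is a free parameter of the simulator, not an
empirical claim: the magnitude of that asymmetry in real Basal Ganglia
recordings is not well quantified, so the default is simply a clearly
detectable ratio.

Defaults reflect a typical externalized-DBS session: 2000 Hz raw
sampling, 58 trials per class, inter-event gaps uniform on the 1–5 s
validity range, cue-to-response latencies 0.3–0.6 s, beta ERD gains
0.5/0.6 (low/high beta), mild alpha ERD (0.8), gamma ERS (1.3/1.2),
delta burst amplitude 1.5, background noise SD 1 with spectral slope
−1, and line amplitude 0.25. Identical configuration and seed give a
bit-identical session.

What the generator does *not* emulate: tremor and other pathological
oscillations, medication state, stimulation artifacts, non-stationary
baselines, electrode drift, or EMG co-recordings. Passing tests on this
simulator therefore demonstrate the pipeline's correctness and its
statistical behavior under controlled conditions — not clinical
performance on patient data.

## Calibration measurement

The generator's gains are verified by an independent oracle: band-pass
filtering (Butterworth, not the WPT path) plus the analytic-signal
envelope, comparing the mean envelope 0–350 ms post-response with the
1–2 s pre-response baseline. One caveat discovered during design: with
inter-event gaps as short as 1 s, the previous trial's modulation tail
overlaps the 1–2 s baseline window and biases the measured ratio toward
1. The calibration test therefore draws gaps from 3–5 s (still within
the protocol's validity range) so the baseline is guaranteed clean;
decoding experiments keep the full 1–5 s range.

# Preprocessing choices

The low-pass is applied forward–backward (`filtfilt`), so the effective
response is the squared magnitude with zero net phase — event timing is
preserved exactly, and an event at `t` seconds indexes sample
`round(256 t)` after resampling. The defaults are order 8 with 0.01 dB
passband ripple: after the double pass this keeps the passband flat
within 1% while attenuating 120 Hz by ≈47 dB. A lower-order design with
the conventional 0.5 dB ripple cannot meet both goals at once (order 4
yields only 26 dB at 120 Hz and ~9% passband droop after the double
pass), which is why the sharper flat design is the default.

The notch is a standard second-order IIR biquad at 50 Hz with quality
factor 30 (≈1.7 Hz bandwidth), also run forward–backward. Q = 30 is a
design choice: narrow enough to leave 40 and 60 Hz content within 5%,
wide enough to suppress realistic line wander. Re-notching an
already-notched signal changes it by less than 0.1% in steady state;
exact idempotence is impossible for any IIR notch because the passband
magnitude is not identically 1.

Resampling to 256 Hz is performed in the Fourier domain by spectral
truncation. For a signal already band-limited to 90 Hz — guaranteed by
the preceding low-pass, against a target Nyquist of 128 Hz — this is the
ideal resampler (it is exact up to the finite-length window), and it
avoids the passband ripple a polyphase FIR stage would add.

# Wavelet packet band decomposition

A level-5 WPT at 256 Hz yields 32 terminal subbands of 4 Hz. The
terminal nodes are not frequency-ordered in the natural tree order
(every high-pass branch mirrors the spectrum); rather than hard-coding
the Gray-code permutation, the package computes each node's equivalent
analysis filter and sorts nodes by measured passband center — a
self-validating construction that the tests cross-check with pure
tones.

Band edges snap to the 4 Hz grid. The 12–13 Hz sliver is indivisible at
this resolution and is assigned to low beta rather than alpha, keeping
the analysis-critical beta range intact; high gamma extends to 92 Hz.
Nodes above 92 Hz are discarded.

The discrete Meyer (dmey) filter pair is the standard 62-tap FIR
approximation. It is only *near*-orthogonal: synthesizing with the
transposed filters leaves reconstruction errors of order 1e−2 after five
levels. The package instead inverts the analysis bank exactly in the
frequency domain — a per-frequency 2×2 polyphase solve, well conditioned
for dmey (the determinant magnitude stays ≈2) — so the packet tree
reconstructs its input to machine precision while the band responses
remain the genuine dmey responses. Signals are zero-padded internally to
an FFT-friendly multiple of 32 and truncated after reconstruction.

Envelopes are computed over the whole recording, not per epoch, to avoid
analytic-signal edge artifacts inside epochs; epochs are cut from the
envelope series afterwards. A 100 ms window at 256 Hz holds 25.6
samples; windows are realized as half-open sample ranges
`[round(256 t_lo), round(256 t_hi))`, i.e. 25 or 26 samples, fixed by
construction.

Trials whose spacing to a neighboring event falls outside the 1–5 s
validity range are flagged and excluded from the feature table, as are
trials whose epoch would extend beyond the recording.

# Base classifiers

The method's defining sizes (hidden units, widths, epochs) are not fixed
by the problem, so they are package defaults chosen for ~70-dimensional
inputs with at most a few hundred trials:

* **FBANN** — one hidden layer of 10 logistic units and a single
  logistic output, trained by full-batch steepest descent on the mean
  squared error (learning rate 0.05, at most 500 epochs). A 10% holdout
  monitors generalization; training stops after 10 stagnant checks. Of
  3 random restarts the design with the lowest monitored error is kept,
  mirroring the protocol of selecting the lowest-error design set.
* **RBFNN** — 20 Gaussian units centered on k-means prototypes; a
  single width proportional to the median inter-center distance, with
  the scale factor (0.5, 1 or 2) picked by inner cross-validation; the
  linear output layer is solved in closed form by ridge-regularized
  least squares — the global minimum of the output-layer problem — and
  the score is clipped to [0, 1].
* **PNN** — Parzen Gaussian kernel density per class with the Bayes
  decision rule; the smoothing parameter is chosen by grid search
  (0.1–2 × the median pairwise distance) on inner cross-validation
  folds. Exact posterior ties resolve to the first class in canonical
  order.

All three see features standardized per dimension with training-fold
statistics; the distance-based RBFNN and PNN require commensurate
scales and the paper-level method leaves scaling open.

# Imbalance handling and a design lesson

Unequal class counts are corrected inside each training fold by the
nearest-neighbor weighted bootstrap: a seed point and its r = 5 nearest
neighbors are combined convexly with weights drawn from a folded
Gaussian, clipped to [0, r] and normalized to sum 1 (the seed point
carries its own weight; if all coefficients clip to zero the draw is
repeated). Every synthetic sample lies in the convex hull of its
neighborhood, and test folds are never augmented — balancing happens
strictly after the cross-validation split, so no synthetic sample can
leak into evaluation.

One consequence surfaced during development: convex combinations of
r + 1 points contract toward the local mean by roughly the square root
of the effective number of contributors, and in 70 dimensions with ~100
trials the "local" neighborhood is nearly global, so synthetic samples
are systematically closer to the class centroid (measured mean radius
ratio ≈ 0.54). The discriminative FBANN and RBFNN tolerate this, but a
Parzen density estimate built on contracted samples concentrates its
mass away from the class boundary and the PNN's stage-1 accuracy
collapsed. The package therefore balances differently by classifier
type: FBANN and RBFNN train on the augmented set, while the PNN
estimates its class densities from original patterns only and balances
through equal class priors — the Bayes-correct mechanism for a
generative classifier.

# Fusion and the two-stage decoder

Each base score in [0, 1] is thresholded at 0.5 (scores ≥ 0.5 code the
event/left class, below 0.5 the rest/right class) and the three binary
votes are fused by plurality; with three voters and two classes two
agreeing classifiers decide and no tie is possible. Stage 1 is trained
with movement trials (response-anchored features) against rest trials
(pre-stimulus features); stage 2 is trained on movement trials only,
left against right. At decode time every trial passes stage 1, and only
trials decided as movement reach stage 2 — rest decisions never invoke
the laterality stage.

# Evaluation statistics

All metrics derive from the 2×2 confusion table. The closed-form AUC,
`(TPR + TNR)/2`, equals balanced accuracy (reported in percent) by
construction, and the identity is asserted on random tables in the test
suite. Cohen's kappa is computed from the C×C agreement matrix with the
standard large-sample standard error
`sqrt(p0 (1 − p0) / N) / (1 − pe)`; the printed form of the variance in
the source material is typographically unrecoverable, so the package
documents and uses this standard estimator. Agreement is flagged above
chance when the 95% CI lower bound exceeds zero. The F-measure and
g-means use the standard definitions (harmonic mean of precision and
sensitivity; geometric means of sensitivity with precision and with
specificity). The composite desirability statistic is the product of
mean/SD ratios of three rate metrics (D1) and of the three balance
metrics (D2), combined as the sixth root of their product — the
geometric mean of the six ratios. Metrics whose denominator is empty are
reported as an explicit not-a-value with a reason code, never imputed.

Per-fold confusion tables are pooled by summation (micro averaging);
per-fold rates are also retained for macro summaries.

# Problem sizes and reproducibility

The shipped tests exercise the full pipeline at three scales: unit
fixtures (tens of trials), a strong-modulation session with beta ERD
gain 0.4 and 100 trials per class for the end-to-end recovery check
(three-class ensemble accuracy ≥ 0.85 at seed 1; the run completes in
well under ten minutes on one CPU), and a 40-trial-per-class null
session (all gains 1, no delta burst) whose stage-1 kappa CI must cover
zero. Every stochastic step — simulation, fold assignment, weight
initialization, k-means, bootstrap draws — derives its seed from the
experiment seed, so a full `run_experiment()` is exactly reproducible.

# Known limitations

* The synthetic generator's realism bounds what the tests can show; in
  particular the laterality contrast and SNR levels are assumptions.
* Band edges are snapped to the 4 Hz dyadic grid (13 → 12 Hz,
  90 → 92 Hz); exact printed edges are unrepresentable at this
  resolution.
* The decoder is strictly offline; no causal filtering or streaming
  support.
* EDF import/export is not provided; sessions exchange as plain CSV
  containers.
* The PNN remains the weakest base classifier on this feature
  distribution — isotropic kernel densities suffer from the many
  uninformative dimensions — which matches its role as one vote among
  three rather than a standalone decoder.
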