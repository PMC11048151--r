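---
title: "Reconstructing missing ECG from PPG: models and methods"
author: "ppg2ecg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing missing ECG from PPG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Long-term electrocardiogram (ECG) monitoring loses segments: electrodes
detach, motion corrupts the trace.  A photoplethysmogram (PPG) recorded
simultaneously — cheap, unobtrusive, robust — carries much of the same
cardiac timing information: each PPG systolic pulse trails the
corresponding ECG R wave by the pulse arrival time (PAT), and the
peak-to-peak interval of the PPG tracks the R-R interval.  `ppg2ecg`
implements a sequence-to-sequence approach to filling ECG gaps from the
PPG: a one-dimensional dual-U-Net ("WNet", optionally with a bidirectional
LSTM bottleneck) is trained to translate 3-second PPG windows into the
simultaneous ECG windows, and the reconstructed windows are stitched and
realigned to the reference by cross-correlation.

## Pipeline

For each paired record (ECG lead II + PPG, 125 Hz):

1. **Filtering.** Zero-phase Chebyshev type-II band-pass, 0.5–20 Hz for
   ECG and 0.5–10 Hz for PPG (`cheby2_bandpass()`).
2. **Alignment I.**  R peaks are detected with the Pan–Tompkins chain
   (`detect_r_peaks()`), systolic peaks with the two-moving-averages block
   method (`detect_systolic_peaks()`).  The PPG is advanced so the third
   systolic peak coincides with its R peak (`align_pair()`), removing the
   PAT.
3. **Normalization and segmentation.**  Both channels are min–max scaled
   to [0, 1] per record; the first 294 s are cut into 98 consecutive
   3-second segments of 375 samples (`segment_record()`).
4. **Splitting.**  The first 60 % of segments train the model, the next
   20 % validate it, the last 20 % are held out for testing
   (`split_segments()`).
5. **Missing data.**  One contiguous gap of 1–4 s of ECG is blanked (zero
   amplitude, mask false) at a seeded uniform position inside the training
   portion (`inject_gap()`).
6. **Training.**  A group model is fit jointly across records with Adam on
   the mean-squared-error objective (`train_model()`).
7. **Reconstruction and evaluation.**  Held-out PPG segments are mapped to
   ECG, stitched (`stitch()`), realigned by cross-correlation
   (`xcorr_align()`, Alignment II), and scored with Pearson's *r*, RMSE,
   PRD and the discrete Fréchet distance (`evaluate_record()`).

## Model

Each U-block takes a (padded) 384-sample sequence through four
encoder blocks — 1-D convolution (kernel 4, stride 2, padding 1), batch
normalization, ReLU — halving length and doubling channels
(32, 64, 128, 256 from a base of 32), then four decoder blocks —
transposed convolution (kernel 4, stride 2, padding 1), batch
normalization, ReLU — with the same-level encoder output concatenated
after each of the first three decoder stages.  Dropout (rate 0.5) is
applied at each U-block bottleneck.  Two U-blocks run in sequence; the
second one's output passes a final 1×1 convolution activated by Tanh and
is cropped back to 375 samples.  The `wnet_bilstm` variant inserts a
single bidirectional LSTM (hidden size 128 per direction) across the 24
bottleneck time steps of the second U-block, between its contraction and
expansion paths.

Architectural choices the reference design leaves open, fixed here once:

* **Depth and width.**  Four levels per U-block from a base of 32
  channels.  These live in `model_spec()` so alternatives are one-line
  changes; kernel 4 / stride 2 and dropout 0.5 are part of the design and
  are rejected unless explicitly overridden.
* **Padding.**  375 is odd, so repeated stride-2 halving requires
  padding.  The input is constant-padded (value 0) by 4 samples left and
  5 right to 384 = 3·2⁷ on entry and cropped on exit.
* **Skips.**  Concatenation skips connect same-level encoder/decoder
  stages *within* each U-block only; there is no skip across U-blocks.
  The topmost decoder stage has no skip (its same-level counterpart would
  be the raw block input).
* **BiLSTM placement.**  "Between the contraction and expansion paths"
  is realized at the bottleneck of the *second* U-block, before dropout.
* **ECG target range.**  The Tanh output is bounded in [−1, 1]; the ECG
  target is min–max normalized to [0, 1] per record so the objective is
  attainable.  (Only the PPG is explicitly normalized in the reference
  description; normalizing the target is this package's assumption.)

## Training

The objective is the mean of squared per-sample differences between the
reference and reconstructed ECG segment.  Gap samples enter the mean as
zero-filled targets by default — the loss definition has no mask term —
and `masked_loss = TRUE` excludes them instead, which is the
physiologically sensible alternative.  Optimization uses Adam
(β₁ = 0.9, β₂ = 0.999, ε = 1e-8; framework-default constants recorded in
the training history) at a learning rate of 0.001 decaying by 0.1 every
100 *epochs* for 500 epochs with batch size 128.  "Every 100 steps" is
read as epochs: with a 500-epoch budget, per-batch decay would freeze the
optimizer within the first epoch.  The returned model is the checkpoint
with minimum validation loss (a selection rule the reference leaves
unstated).  One model is trained jointly across all records (a group
model), not per subject.

The engine is written directly on Armadillo in single precision; batch
normalization uses running statistics (momentum 0.1) in evaluation mode,
and all randomness — weight initialization, dropout, batch shuffling —
derives from named child seeds of the run seed (`derive_seed()`), so a
run is bit-reproducible from its manifest.

## The synthetic generator

Real paired recordings (e.g. intensive-care waveform archives) cannot be
redistributed with a package, so `ppg2ecg` ships a generator
(`synth_params()`, `gen_record()`) that emulates exactly the features the
pipeline depends on:

* a beat train with Gaussian inter-beat-interval jitter
  (default SD 0.04 s, a typical short-term heart-rate variability) and a
  0.3 s minimum interval;
* ECG morphology as five Gaussian deflections per beat — P (0.15, −0.20 s,
  0.04 s), Q (−0.15, −0.04 s, 0.012 s), R (1.0, 0, 0.014 s), S (−0.2,
  0.035 s, 0.014 s), T (0.3, 0.28 s, 0.06 s) as (amplitude, offset,
  width) — with the R wave dominant so beat timing is well defined;
* a PPG whose systolic pulse (width 0.09 s) trails each R peak by a fixed
  PAT (default 0.24 s) plus a smaller dicrotic pulse (amplitude 0.25,
  delay 0.28 s);
* additive white Gaussian noise (default SD 0.02 relative to the unit R
  amplitude) and an optional 0.25 Hz baseline-wander sinusoid that
  exercises the 0.5 Hz high-pass edge.

A Gaussian-sum morphology was chosen over a dynamical-system simulator
because every downstream property (argmax positions, lags, counts) is
analytically checkable.  The first beat sits 0.5 s into the record so no
edge beat is truncated.  What the generator does *not* emulate — and what
passing tests therefore do not demonstrate — includes arrhythmias and
ectopy, pathological or drifting PPG morphology, motion artifacts,
sensor-specific noise spectra, and inter-subject morphology variation
beyond heart rate.  Results on synthetic corpora are a verification of
the pipeline's mechanics, not a clinical validation.

## Numerical choices

* **Filter realization.**  A Chebyshev type-II prototype is specified by
  its stopband.  To realize a stated *passband*, the 40 dB stopband edges
  are placed at 0.4× the lower and 1.8× the upper passband edge; applied
  forward–backward the net response is unit gain mid-band (≥ 0.9 at the
  passband edges of interest) with zero phase, which Alignment I's peak
  matching requires.  Stopband attenuation (unstated in the reference
  design) is fixed at 40 dB.
* **Indexing.**  All R-level sample indices are 1-based (R idiom), with
  time t = (i − 1)/fs.  The C++ engine converts internally.
* **Peak detector constants.**  Pan–Tompkins: 5–15 Hz band-pass,
  derivative, squaring, 150 ms integration, adaptive dual thresholds with
  search-back, 200 ms refractory, detections refined to the band-passed
  ECG maximum.  Block method: 0.5–8 Hz band-pass, clipped squaring,
  111 ms / 667 ms moving averages, offset 2 % of the mean squared
  amplitude, minimum block width 111 ms, 300 ms minimum separation.
* **Alignment II.**  Lag search is ±1 s (±125 samples) by default; the
  shifted series is edge-value padded so all four metrics see the same
  sample count aligned and unaligned; ties prefer the smallest |lag| and
  lag 0 is always a candidate, so realignment cannot reduce *r* below the
  unaligned value.
* **Fréchet distance.**  The printed formula in the reference description
  (same index on both curves) is not a standard definition; the package
  implements the standard discrete Fréchet distance over monotone
  couplings (dynamic programming), which realizes the stated
  "minimizes the maximum distance" intent.  Distances are absolute
  amplitude differences.
* **Degenerate inputs.**  Constant signals are rejected by
  normalization, correlation and cross-correlation; an all-false mask is
  rejected by the masked loss; records shorter than the configured usable
  span are rejected at segmentation.

## Problem sizes in tests and the acceptance script

The reference experimental scale (146 records, 500 epochs) is a
multi-hour GPU workload; this package's own verification scale, chosen
once, is: 10 synthetic records (294 s each, noise SD 0.02, heart rates
60–90 bpm), a 2 s gap, WNet trained 150 epochs at batch 32 for the
parameter-recovery check (held-out mean *r* ≥ 0.7 after Alignment II, a
bar set for this synthetic corpus, plus the qualitative finding that
realignment does not reduce *r*); and 6 records / 60 epochs for the
end-to-end acceptance script.  Unit tests use 20–60 s records and
2–8-epoch budgets.

A note on the single-pair overfit sanity check (driving the training loss
below 10⁻³ on one repeated segment within 500 steps): at the full
training's default learning rate this is an under-powered probe, so the
probe uses a faster schedule (2e-3 decaying after 200 steps for WNet,
1e-2 after 250 for WNet-BiLSTM) with the threshold and step budget
unchanged.  Analytic gradients are verified against central finite
differences in the test suite.

## Known limitations

* The synthetic corpus is far easier than intensive-care data: one
  morphology family, stationary noise, no artifacts.  Absolute metric
  values reported by the acceptance run are not comparable to values on
  clinical data.
* The WFDB reader supports the common format-16 single-file layout only.
* Metrics default to the whole test portion per record; a windowed
  variant can be had by evaluating `evaluate_record()` over slices.
* No statistical comparison between the two variants is performed.
* WNet-BiLSTM convergence is sensitive to the weight-initialization seed:
  some initializations put the LSTM gates in a slow-learning regime, and
  short training budgets then under-use the bottleneck.  (The reference
  results also found the BiLSTM variant no better than plain WNet.)
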