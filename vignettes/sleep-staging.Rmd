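---
title: "Spectrogram-based sleep staging: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrogram-based sleep staging: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`somnet` classifies 30-second single-channel EEG epochs into the five AASM
sleep stages (W, N1, N2, N3, REM) from time-frequency images, using a
compact residual CNN for per-epoch features and a bidirectional LSTM over
10-epoch sequences for the transition structure of sleep. This vignette
explains the model and its assumptions, the parameters that matter, the
numerical choices, what the synthetic generator does and does not emulate,
and the design decisions taken where the architecture left room.

## From signal to image

An epoch arrives as `30 * rate` microvolt samples at 100 Hz (Sleep-EDF
convention), 125 Hz (SHHS) or already 64 Hz. The pipeline is:

1. **Resample to 64 Hz** (`resample_to_64()`), giving 1920 samples.
   Sleep-relevant activity lies below ~30 Hz, so 64 Hz retains everything
   of interest; the polyphase resampler of the `signal` package provides
   the anti-aliasing filter. Upsampling is refused — rates below 64 Hz
   would fabricate bandwidth.
2. **Short-time power** (`stft_power()`): Hann window of 256 samples
   (4 s), hop 128, one-sided spectrum including the Nyquist bin — a
   129 × 14 grid at 0.25 Hz × 2 s resolution, in dB
   (`10 log10`, floored at −120 dB so silent bins stay finite).
3. **Rasterize** (`rasterize()`): per-image min–max normalization to
   `[0, 1]`, bilinear resize to a 100-dot frequency axis (32 Hz at the
   top, as a rendered figure would be) by an 80-dot time axis, then a
   256-entry viridis lookup. The colormap table ships with the package as
   a CSV asset, so the output never depends on a plotting library.
4. **Crop** (`crop_spectrogram()`): keep rows `[14, 90)` and columns
   `[11, 71)` — the region a rendered figure devotes to data rather than
   margins — producing the fixed 76 × 60 × 3 input.

Two properties follow by construction and are enforced by tests: the
output shape is identical for every supported source rate, and scaling
the input amplitude leaves the image unchanged (log power is shifted by a
constant that min–max normalization removes). Consequently the classifier
cannot — and need not — rely on absolute amplitude calibration.

A note on the raster orientation: the crop box spans 76 dots vertically,
which only fits an image whose *frequency* axis carries 100 dots; the
time axis carries 80. The geometry helpers `image_row_for_freq()` and
`image_col_for_time()` expose the exact pixel mapping, and the test suite
uses them to verify that pure tones at 5, 13 and 25 Hz land on the
expected rows within 1 Hz.

Rendering choices that a plotting pipeline would make implicitly are made
explicitly here: normalization is per image (a per-recording alternative
would preserve relative amplitude between epochs at the cost of
inter-subject variability; per-image is what figure rasterization does
and what the amplitude-invariance property requires), interpolation is
bilinear on an align-corners grid, and the colormap lookup quantizes to
256 levels.

## The network

`model_config()` defaults describe the full model:

* five convolutional blocks with channels 16, 16, 32, 32, 64 — one 3 × 3
  stride-1 "same" convolution per block, exact-erf GELU
  (`x * pnorm(x)`), 2 × 2 stride-2 max pooling (ceil-mode for odd sizes),
  batch normalization, dropout with keep-probability 0.5. Block 5 adds a
  3 × 3 stride-1 average pool before normalization. Spatial sizes run
  76×60 → 38×30 → 19×15 → 10×8 → 5×4 → 3×2.
* skip additions: the input of block 2 is added to its conv+GELU
  activation before pooling, and likewise for block 4. At these points
  the operands genuinely share shape — channel pairs (16, 16) and
  (32, 32) are a configuration invariant — so no projection is needed,
  keeping the additions parameter-free. (Adding *after* pooling is
  impossible without a projection: consecutive block outputs differ by a
  factor-2 spatial downsampling.)
* global average pooling to a 64-d feature per epoch;
* a 2-layer bidirectional LSTM, hidden size 128 per direction, over
  sequences of 10 consecutive epochs; per time step the two directions of
  the last layer concatenate to 256-d and feed a softmax over 5 stages.
  `lstm_layers` of 0, 1 or 3 give the ablation variants (0 applies the
  softmax directly to each 64-d feature — no sequence context);
* an auxiliary softmax head on the 64-d features, active only in
  training: `Loss = Loss_main + aux_weight * Loss_aux` with
  `aux_weight = 0.5`, both terms mean cross-entropies with probabilities
  clamped to `[1e-12, 1]`. It anchors feature quality independently of
  the recurrent path and is removed at evaluation.

The per-block internals beyond the first convolution's 16 channels are
under-determined by the architecture's published description; the widths
above were chosen to satisfy the stated constraints (16-channel first
conv, 64-d pooled feature, projection-free residual pairs) and to land
the total budget at the advertised ~0.6 M trainable parameters —
`count_parameters(model_config())` gives 628,954. The dropout notation
"p = 0.5" is read as keep-probability; the two readings coincide at 0.5.

Initialization: Glorot-uniform for convolutional and dense weights,
per-gate orthogonal recurrent kernels, zero biases, unit/zero batch-norm
scale/shift; everything is a deterministic function of the seed.

### Training versus evaluation, and batch-norm calibration

Training mode uses batch statistics, dropout, and both heads; evaluation
uses running moments, no dropout, and the main head only — a pure
function of its input.

One consequence of the block order (…, batch norm, then dropout) deserves
attention. The running moments that batch normalization accumulates
during training describe activations *downstream of dropout in every
preceding block*. With keep-probability 0.5 in all five blocks, inverted
dropout doubles second moments at each stage; once dropout is switched
off for evaluation the compounded mismatch leaves the stored moments
describing a distribution the network never sees, and held-out
predictions collapse. `calibrate_bn()` therefore re-estimates the running
moments immediately before evaluation: a handful of training batches are
forwarded with dropout disabled and the clean per-batch moments averaged.
`train_fold()` does this automatically before every test-set evaluation;
call it yourself after any custom training loop. Calibration touches no
trainable parameter.

## Training protocol

`train_fold()` implements the protocol: sequences of 10 consecutive
epochs per subject (a trailing remainder shorter than 10 is dropped for
training and scored once via a tail-aligned window at evaluation),
mini-batches of 5 sequences (50 images), a configurable number of passes
over the fold's training sequences with reshuffling each pass, evaluation
on the test fold every `eval_every = 3` passes, and retention of the best
test report (highest accuracy, ties broken by macro-F1). The reference
protocol uses 150 passes; desk-scale studies converge far sooner (see
below).

The optimizer is not pinned down by the architecture description; the
package uses Adam with learning rate `1e-4` by default, no weight decay,
and a global gradient-norm clip of 5 — all configurable in
`train_config()`. Cross-validation (`make_folds()`) is subject-wise by
default: every subject's epochs belong to exactly one fold, reducing to
leave-one-subject-out when subjects equal folds. The epoch-wise mode
(for cohorts smaller than the fold count) deals whole 10-epoch sequence
blocks, never single epochs, so sequence integrity survives the split;
blocks are shuffled with the run seed before assignment.

## The synthetic generator

`generate_dataset()` makes the whole pipeline testable without clinical
data. Each stage has a spectral recipe built from its scoring hallmarks:

| stage | band (Hz) | rel. amplitude | duty | extras |
|-------|-----------|----------------|------|--------|
| W | 8–13 | 1.0 | 0.85 | — |
| N1 | 4–7 | 0.8 | 0.85 | — |
| N2 | 4–7 | 0.5 | 0.90 | 2–4 spindle bursts, 12–14 Hz, 0.5–1.5 s, amp 1.3 |
| N3 | 0.5–2 | 2.5 | 0.90 | — |
| REM | 4–8 | 0.75 | 0.85 | — |

plus Gaussian broadband noise (relative sd 0.40–0.45) and a per-subject
amplitude factor drawn from `[0.8, 1.25]`. Amplitudes are in units of
20 µV, putting signals in a plausible scalp-EEG range; the exact values
are generator constants, not physiological claims — chosen once so that
stages are separable but not trivially so. In particular **N1 and REM are
deliberately near-twins spectrally** (4–7 vs 4–8 Hz, similar amplitude):
exactly the pair that trips up human scorers and per-epoch classifiers.
Disambiguating them requires context, which is what makes the ablation
informative.

Hypnograms come from a first-order Markov chain whose default matrix is
ordinally constrained by the transition regularities of real sleep:
wakefulness hands over to N1 an order of magnitude more often than to REM
(0.105 vs 0.010 per epoch), N1 feeds N2 heavily (0.32) while REM almost
never does (0.02), and deep sleep is persistent. Entries are
configuration, not estimates. Nights start awake.

What the generator does **not** emulate: K-complex and sawtooth
morphology, artifacts and arousals, age and pathology effects, EOG/EMG
context, or the severe class imbalance of real cohorts (N1 can be ~3% of
a clinical night; the chain's stationary distribution is milder). A model
that excels here has demonstrated that the pipeline, optimization and
sequence learning work — not that clinical-grade accuracy on Sleep-EDFX
or SHHS follows. Those benchmarks require the real recordings and
GPU-scale cross-validation, which is precisely why the package's
acceptance study is synthetic.

## Desk-scale study sizes

The test suite's end-to-end study uses 20 synthetic subjects × 100 epochs
(16 train / 4 test, seed 42), 9 training passes at learning rate `1e-3`
for the generalization check, and 6 passes per run for the 3-seed
with/without-BiLSTM ablation — sizes chosen so the whole suite runs
comfortably on one CPU core. On this task held-out accuracy crosses 90%
within the first three passes, so the shortened schedules measure the
settled regime, not a lucky snapshot.

## Numerical notes and edge cases

* STFT of an all-zero signal sits entirely at the −120 dB floor; a
  constant (all-equal) power grid rasterizes to colormap entry 0.
* Max pooling uses ceil-mode windows, so odd spatial sizes pool partial
  windows rather than discarding rows; the 3 × 3 average pool in block 5
  averages over in-bounds neighbours only.
* Batch-norm uses biased batch variance for normalization and unbiased
  running variance (the usual convention), ε = 1e-5, momentum 0.1.
* Softmax subtracts the column maximum before exponentiation; losses
  clamp probabilities at 1e-12.
* Orthogonal recurrent initialization fixes the QR sign ambiguity so
  results are identical across BLAS implementations.
* All stochastic steps (initialization, shuffling, dropout, the
  generator) draw from R's RNG under explicit seeds; RNG state is saved
  and restored around seeded helpers so library calls never perturb a
  caller's stream.
* EDF signals are 16-bit: round-tripping through `write_edf()` /
  `read_edf()` is exact only to the quantization step of the configured
  physical range. Stage annotations ride in the EDF+ annotation channel
  or in a plain hypnogram CSV.

## Known limitations

* Single channel, single modality: no EOG/EMG fusion, no artifact
  rejection.
* The per-block internals of the feature extractor are a reconstruction
  constrained by the published shapes and parameter budget; other
  configurations satisfy the same constraints.
* The evaluation-time batch-norm calibration adds a small cost per
  evaluation (a dozen forward batches) and requires access to training
  images wherever the model is evaluated.
* Training is CPU-bound R/C++; it is meant for desk-scale studies and
  method work, not for training on hundreds of clinical nights.
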