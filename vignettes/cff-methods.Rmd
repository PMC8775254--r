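---
title: "Concatenate feature fusion for sEMG gesture recognition: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concatenate feature fusion for sEMG gesture recognition: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cffemg)
```

## The model

Surface EMG is the skin-level superposition of motor-unit action potentials;
for pattern recognition it behaves like band-limited noise whose *amplitude
envelope* carries the gesture information. A recognizer segments the
C-channel signal into 250 ms windows advanced every 50 ms, reshapes each
`N × C` window into a `W × H × C` frame (with `W·H = N`), and classifies
frames with a time-distributed CNN followed by an LSTM.

Dimensionality reduction inside the CNN is where information dies:

* featurewise max-pooling, `z_t = max{y_t, …, y_{t+s-1}}`, keeps the dominant
  amplitude of each window per channel but is invariant to any reordering
  inside the window — temporal order is discarded, `s − 1` values per step;
* a feature-mixing 2-stride convolution, `y_t = Σ_j c_j x_{s(t−1)+j}`, keeps
  context but maps distinct inputs to equal outputs (`find_collision()`
  constructs such pairs for any kernel of size ≥ 2 by transferring mass
  between coordinates with nonzero weights).

The CFF block runs both operators in parallel on the same map and
concatenates channels, pooling first. Its pooling branch contributes zero
trainable parameters; all of the block's parameters sit in the convolution
branch. After one fusion at the standard 64-filter width the map has 128
channels. Because `n` stacked 1-stride convolutions see `n(k−1)+1` inputs
(`receptive_field()`), losing `s − 1` of those positions at the first
reduction is what the fusion prevents.

Both classifier variants share the stack
`conv(64, k=3) → BN → ReLU → [reduction] → conv(64, k=3) → BN → ReLU →
max-pool → flatten → FC 512 → FC 512 → FC 128 → LSTM 512 (dropout 0.5) →
FC → softmax`; the RCNN's first reduction is a plain max-pool, the
CFF-RCNN's is the CFF block. Training uses SGD with momentum 0.95, learning
rate 0.002, weight decay 0.0005, minibatches of 20, and a cross-entropy loss
of the form `−[y·log ŷ + (1−y)·log(1−ŷ)]` averaged over the softmax outputs.

## Numerical and design choices

Choices the architecture description leaves open, fixed here once:

* **Spatial bookkeeping.** All convolutions are same-padded; all pooling
  layers (including the CFF pooling branch) use ceiling arithmetic, keeping a
  truncated edge window when an extent is odd. Both reduction branches then
  emit exactly `ceiling(L/2)` positions, which the concatenation requires,
  and replacing the CFF block by a plain pool reproduces the RCNN layer for
  layer — a property the test suite asserts.
* **CFF convolution branch.** ReLU-activated with bias, *not*
  batch-normalized (batch normalization is reserved for the 1-stride
  convolutions; a `branch_bn` switch exists). The analytic `cff_block()`
  operator, by contrast, is bias-free and pre-activation, matching the
  collision algebra.
* **Frame flattening.** `reshape_frame()` reads the window time-major and
  fills frames height-fastest (`frame[w, h, c] = buffer[((c−1)W + (w−1))H + h]`).
  Any fixed bijection would do; this one keeps channels intact in the
  2 kHz layout (`500×12 → 5×100×12`) and folds channels into space in the
  100 Hz layout (`25×10 → 5×25×2`). The inverse is exact and tested bit-for-bit.
* **Window labels.** A window takes its majority per-sample label; a
  configurable purity threshold (default: majority, i.e. ≥ 50%) drops
  ambiguous windows, and rest-majority windows are kept as a class by
  default (`drop_rest` excludes them). The sources are silent on both
  points; majority labeling is common sEMG practice and deterministic.
* **Standardization.** Per-channel z-scoring fitted on training frames only,
  with an optional min–max step; statistics are serializable and applied
  unchanged to held-out data. A zero-variance channel gets unit scale and a
  warning.
* **LSTM sequences.** The sequence length `T` is configurable and defaults
  to 1 (each window classified from its own frame); the time-distributed CNN
  applies identically per frame for any `T`.
* **Weight initialization** is fan-based (He for conv/dense, uniform ±1/√U
  for the LSTM, forget-gate bias 1), seeded from the experiment seed.
* **Signed-rank test.** Zero differences dropped, midranks for ties, and the
  exact permutation distribution (dynamic programming over doubled ranks)
  for up to 25 retained pairs; beyond that, a tie-corrected normal
  approximation with continuity correction. The two-sided p doubles the
  smaller tail and caps at 1.

## What the synthetic generator emulates

`generate_recording()` models sEMG as class- and channel-specific amplitude
envelopes (flat, rising/falling ramps, burst) modulating zero-mean Gaussian
noise, plus background noise everywhere at a set SNR, arranged in the
movement/rest repetition protocol of the benchmark acquisitions. The default
conditions are G = 6 classes, C = 4 channels, 200 Hz, 6 repetitions of 1 s
movement with 0.5 s rest, and 20 dB SNR — small enough that complete
generate–segment–train–compare cycles run in minutes on one CPU, and 20 dB
being a clean laboratory-grade surface recording.

It does **not** simulate motor-unit recruitment, electrode lift-off,
power-line interference, or fatigue; passing tests show that the pipeline
and the architecture behave as designed, not that the published benchmark
accuracies transfer to clinical data.

`make_confusable_pair()` sharpens the generator into the adversarial case
for amplitude-only processing: two classes with equal envelope peaks whose
ramps rise (class 1) or fall (class 2) with a period equal to the analysis
window. Any full window then contains exactly the same multiset of envelope
values for both classes — per-window maxima and mean absolute value are
uninformative by construction — while the temporal profile inside the frame
still identifies the class.

## The desk-scale directional experiment

`confusable_experiment()` is the package's qualitative counterpart of the
full benchmark comparison: on the confusable pair it trains both variants
with identical seeds and hyperparameters and asks whether the CFF-RCNN
matches or exceeds the RCNN at equal epochs, and whether an amplitude-only
baseline (per-channel window maxima — precisely the statistic a full-window
max-pool retains — classified with LDA+KNN) stays at chance.

Two protocol points matter and are deliberate:

* **Repetition-disjoint evaluation.** Consecutive 250/200 ms windows share
  80% of their samples. A window-level random split therefore places
  near-duplicates of every held-out window in the training set, and the
  comparison degenerates into a memorization contest that favors the more
  shift-invariant (pooling-only) model. The experiment instead holds out
  whole repetitions in a 3-fold cross-validation, evaluating every window
  exactly once on movement executions the model never saw; both
  architectures share folds, so the comparison is paired. (The window-level
  `random_window` split remains the package default elsewhere, matching the
  published protocol; `by_repetition` is the recommended honest setting.)
* **A capacity-limited model.** At desk scale (238 windows, 2 classes) the
  full 512-unit stack memorizes the training set in a few epochs, and the
  reduction layer is never the bottleneck — the regime the fusion targets
  (50+ classes, where information lost at the first reduction is
  irrecoverable) is gone. The experiment therefore uses reduced widths
  (8 conv filters, FC 16/16/8, LSTM 6, 30 epochs), chosen so final training
  accuracy stays well below 1. Problem sizes throughout the tests follow the
  same principle: large enough to exercise every operator, small enough for
  single-CPU runs.

Under that protocol the CFF-RCNN matches or exceeds the RCNN in the large
majority of seeds while the amplitude baseline stays near 0.5 — the
direction, not the magnitude, of the full-scale findings. The test suite
asserts exactly this (5 seeds, ≥ 4 wins-or-ties, baseline within ±0.1 of
chance on average), and `scripts/acceptance.R` recomputes it from any seed.

## Known limitations

* The network engine is plain R with BLAS matrix products; it is sized for
  the desk-scale experiments, not for the full benchmark databases.
* The binary-style cross-entropy printed in the training recipe is applied
  verbatim to the softmax outputs; the more common categorical form differs
  only in the `(1−y)` term and was not needed.
* The `.mat` reader covers little-endian numeric MAT v5 variables
  (uncompressed or zlib-compressed) — sufficient for the benchmark field
  layout and for `scipy.io` interchange, nothing more.
* Wall-clock timings recorded in training histories are informational; no
  test or reported number depends on them.
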