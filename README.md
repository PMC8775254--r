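# cffemg

Concatenate-feature-fusion networks for multichannel surface-EMG (sEMG)
hand-gesture recognition, in pure R.

## The problem

Gesture recognizers built on sEMG segment the multichannel signal into short
overlapping windows (here 250 ms with a 200 ms overlap), reshape each window
into a small image-like frame, and classify frames with a convolutional
feature extractor feeding a recurrent sequence recognizer (an RCNN). The
weak point of that stack is the dimensionality-reduction layer:

* **Max-pooling** keeps, per channel, only the largest value in each spatial
  window — `z_t = max{y_t, …, y_{t+s-1}}`. It is parameter-free and preserves
  signal amplitude, but it is *order-invariant inside the window*: reorder
  the inputs and the output does not move, so temporal structure is lost.
* **A strided convolution** `y_t = Σ_j c_j x_{s(t-1)+j}` mixes neighbouring
  samples and keeps contextual (temporal) information, but it is *ambiguous*:
  completely different inputs can map to the same output (with kernel
  `(-1, 1, 2)`, both `(1, 1, 1)` and `(3, 1, 2)` give 2).

The **CFF (concatenate feature fusion) strategy** runs both reductions in
parallel on the same map — a size-2 max-pooling and a 2-stride convolution —
and concatenates their channels (pooling channels first). Inputs that
collide under either branch alone are separated by the fused map. A
**CFF-RCNN** is an RCNN whose first reduction is a CFF block; at the standard
width, 64 pooled channels plus 64 convolution filters give a 128-channel
fused map. Stacked 1-stride convolutions have receptive field `n(k-1)+1`,
so a single pooling step discards `s-1` of those positions — the loss the
fusion avoids.

The package provides:

* `windowing` — labeled recordings, sliding windows, frame reshaping (both
  the 2 kHz `(5×100×12)` and the 100 Hz `(5×25×2)` layouts), leakage-safe
  standardization, one-hot encoding;
* `cff core` — `max_pool()`, `strided_conv()`, `find_collision()`,
  `receptive_field()`, `cff_block()`;
* `models` — trainable RCNN and CFF-RCNN classifiers on a self-contained,
  gradient-checked network engine (conv/BN/ReLU/pool/CFF/dense/LSTM,
  SGD with momentum);
* `features` — MAV, ZC, SSC and WL features with PCA/LDA + KNN and
  dense-network baselines;
* `synthetic` — an amplitude-modulated-noise sEMG generator with NinaPro-style
  repetition protocol, including *order-confusable* class pairs whose windows
  share amplitude content and differ only in temporal order;
* `experiments` — training, stratified/repetition-disjoint k-fold CV, exact
  Wilcoxon matched-pairs signed-rank comparison, efficiency reports, and a
  NinaPro-style `.mat` import/export path.

## Worked example

```r
library(cffemg)

## an order-confusable two-class recording: rising vs falling amplitude
## ramps with identical per-window amplitude content
spec <- make_confusable_pair(synthetic_spec(seed = 1))
rec  <- generate_recording(spec)
rec
#> <raw_recording> subject 1: 3600 samples x 4 channels @ 200 Hz, 2 gesture classes

ws <- sliding_windows(rec, window_config(drop_rest = TRUE))
ws
#> <window_set> 238 windows of 50 samples (hop 10) from subject 1

## the amplitude statistic a full-window max-pool keeps is identical for
## the two classes ...
envA <- class_envelope(spec, 1); envB <- class_envelope(spec, 2)
all.equal(sort(envA[1:50, 1]), sort(envB[1:50, 1]))
#> [1] TRUE

## ... so an amplitude-only classifier is at chance, while the temporal
## models are not; CFF-RCNN vs RCNN at equal epochs, repetition-disjoint:
res <- confusable_experiment(seed = 1)
unlist(res[c("acc_cff", "acc_rcnn", "acc_baseline")])
#>      acc_cff     acc_rcnn acc_baseline
#>    0.6596639    0.5756303    0.5378151
```

The fused map geometry and the collision construction:

```r
dim(cff_block(matrix(rnorm(640), 10, 64), array(rnorm(3*64*64), c(3, 64, 64))))
#> [1]   5 128
find_collision(c(-1, 1, 2), c(1, 1, 1))$x_prime
#> [1] 3 1 2
receptive_field(2, 3)
#> [1] 5
```

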