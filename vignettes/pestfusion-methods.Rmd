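---
title: "Multi-scale vision–sensor collaborative pest recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale vision–sensor collaborative pest recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pestfusion)
```

## The problem

Small-target crop pests — aphids, thrips, whiteflies, leafhoppers, spider
mites, leaf beetles — occupy a tiny fraction of image pixels (typically
under ~2%), sit on cluttered leaf textures, and aggregate on leaf
undersides where occlusion is frequent. Their occurrence co-varies strongly
with instantaneous microclimate: temperature, relative humidity and
illumination shape their acute behaviour. Image-only classifiers lose these
targets under repeated downsampling and ignore the ecological prior.

`pestfusion` implements an image-level, six-class pest classifier that
fuses both modalities: a multi-scale convolutional pyramid preserves
fine-grained evidence, and standardized environmental sensor readings act
as a conditional prior that modulates the visual features channel-wise
(FiLM-style gating), with a collaborative head aligning the two modalities
across scales.

## Preprocessing pipeline

The order is fixed: outlier removal → gap interpolation → image–sensor
alignment → standardization.

* **Resolution normalization.** All images are bilinearly resampled to
  `H0 x W0`. The resampler is half-pixel-centred with edge clamping (the
  `align_corners = FALSE` convention); the unit tests pin this convention
  against a direct weight-sum oracle, including the `2 -> 4` upsampling
  case whose interior samples fall at offsets 0.25 / 0.75.
* **Small-target enhancement.** `crop_and_rescale()` extracts a 0-based,
  half-open window `[x, x+w_c) x [y, y+h_c)` and rescales it to the full
  frame, magnifying target pixel fractions; `random_scale_perturbation()`
  draws `alpha ~ U(alpha_min, alpha_max)` (defaults 0.8–1.2), rescales, and
  centre-crops/zero-pads back so batch geometry is constant. Both are exact
  no-ops at their identity parameters.
* **Outlier rule.** A record is flagged when
  `|s_k(t) - mu_k| > lambda * sigma_k` with `lambda = 3` by default.
  `sigma_k` uses the *population* formula (divide by *n*); the tests pin
  this choice. Statistics are computed per acquisition session when a
  session column is available, so a level shift between sites is not
  mass-flagged. Flagged records are treated as missing.
* **Interpolation.** Interior gaps are filled linearly against the
  timestamp axis; records outside the observed range take the nearest
  observed value, since linear interpolation is undefined there.
* **Alignment.** Each image takes the sensor record with the nearest
  timestamp, required to deviate by less than `delta_t` (default 600 s, one
  sampling period). Equidistant ties resolve to the earlier — causally
  available — record.
* **Standardization.** Channels are z-scored with statistics fitted on the
  training partition only and reused verbatim for validation and test
  data; the test suite asserts this leakage guard.

## The network

At reference scale, a `64 x 64 x 3` input produces a four-level pyramid
with spatial sizes (64, 32, 16, 8) and channel widths (64, 128, 192, 256):
a two-convolution stem followed by three stride-2 stages (3x3 kernels,
batch normalization, ReLU). Level 4 carries a global-context branch — its
globally pooled descriptor passes a dense layer and is broadcast-added
back — realizing the global-receptive-field scale of the design.

* **Channel attention.** Each level is gated by
  `w = sigmoid(W2 ReLU(W1 z))` computed from its pooled descriptor `z`,
  with bottleneck ratio 4 (squeeze-and-excitation form). The printed
  design only fixes the pooled-descriptor/sigmoid structure; the ratio is
  a package choice.
* **Cross-scale fusion.** Attention-weighted levels are 1x1-projected to
  256 channels, bilinearly upsampled to level-1 size, and combined as a
  *convex* combination `F_ms = sum_l alpha_l proj(F_l)` where
  `alpha = softmax(logits)` is learnable — the weights sum to 1 at every
  training step by construction. A cross-scale relational unit (one 3x3
  convolution + ReLU, toggleable) refines the fused map. The projections
  and the upsampling realize the "scale alignment operators" that the
  weighted sum requires; the equal-shape requirement is not otherwise
  specified in the design, so this is the package's resolution.
* **Environmental encoder.** The standardized 3-vector passes a
  3 → 32 → 128 ReLU trunk; per-level sigmoid heads emit channel gates
  `g_l` in (0,1), the level-4 head having the printed 128 → 256 shape.
  Modulation multiplies channels: `F~[h,w,c] = g_c F[h,w,c]`, leaving
  spatial structure untouched; per-channel energies scale exactly by
  `g_c`.
* **Reconciling the fused-map and per-level narratives.** One part of the
  design modulates the fused map (64 x 64 x 256); the head consumes four
  modulated levels. The package applies modulation per level via heads
  sharing the trunk, uses the 256-wide head to also modulate `F_ms`, and
  re-injects the modulated fused map as a residual added to the head's
  compressed representation. This keeps every fusion parameter trained in
  the full model and gives the multi-scale branch a role the "w/o
  multi-scale" ablation can remove meaningfully; it is the package's own
  reconciliation of the two narratives.
* **Collaborative head.** The sensor vector is encoded 3 → 32 → 64 to
  `u`; per-level projections `c_l = P_l u + q_l` broadcast spatially to
  gates `G_l`; conditional gating with residual injection
  `M_l = F~_l + ReLU(conv1x1(F~_l ⊙ G_l))` keeps the identity path intact
  at a zero gate. Levels upsample to level-1 size, concatenate to 640
  channels, compress 640 → 256 (1x1 conv + ReLU), add the modulated fused
  map, global-average-pool to `z`, and classify 256 → 128 → 6 with
  softmax.

All sigmoid/ReLU role assignments follow the convention that squashing
nonlinearities produce gates and ReLU produces features; the source design
names these only as "nonlinear activation" / "normalization mapping".

### Ablation variants

`build_variant()` exposes the component ablations: `no_multiscale`
(classify from modulated level-4 features alone, attention kept),
`no_sensor_prior` (all modulation gates fixed at 1; the collaborative head
still consumes the sensor vector — only the prior-modulation mechanism is
removed), `no_collab_head` (classify from the pooled, modulated fused
map), `concat_fusion` (all conditional gating replaced by concatenating
the raw standardized sensor vector to the pooled feature), and
`vision_only` (`no_sensor_prior` + `no_collab_head`; provably independent
of the sensor input). Parameters exist only where a variant consumes them,
so gradient-flow tests can assert that no branch is dead.

### Implementation

No deep-learning framework is available to (or needed by) the package:
layers, batch normalization, attention, softmax cross-entropy and Adam are
implemented over plain BLAS matrix operations with a small reverse-mode
tape (`R/autograd.R`). Convolutions use im2col with cached index plans;
bilinear upsampling inside the network is the same half-pixel operator as
the image resampler, applied as a per-sample pixel-space linear map. Every
parameter group's gradient is validated against central finite differences
in the test suite.

Two knobs scale the topology for desk-size experiments without changing
its shape: `scale_factor` multiplies the spatial sizes and `width_factor`
the channel widths. All printed-dimension tests run at factors 1; training
experiments in the test suite run at 1/4 + 1/4 (16 x 16 inputs, 163k
parameters), sizes chosen so the full stochastic study completes on a
single CPU in minutes. Batch-norm inference statistics are re-estimated by
a deterministic pass over the training data after the final (or
best-validation) weights are fixed, which removes the lag of momentum
tracking on short runs.

## Training and evaluation protocol

* **Objective and optimizer.** Softmax cross-entropy under seeded
  mini-batch Adam; the design names only a gradient-based optimizer, so
  defaults `learning_rate = 1e-3`, `batch_size = 16`, `epochs = 50` are
  package choices, all config-exposed. With a validation set the learning
  rate halves after `lr_patience` epochs without macro-F1 improvement and
  the best-validation weights are restored; without one, a single step
  decay fires at 75% of the epochs. Trailing mini-batches smaller than
  half a batch merge into their predecessor so batch statistics stay
  meaningful.
* **Grouped splitting.** Samples from one acquisition group (plot x
  session) never straddle partitions: greedy largest-first allocation
  targets 70/15/15 sample shares exactly for equal groups and within one
  group size otherwise. Grouped 5-fold CV partitions the training groups
  the same way. Both are hard leakage guards, asserted in tests.
* **Metrics.** One-vs-rest Accuracy/Precision/Recall/F1 per class from the
  confusion matrix, reported in two aggregation flavours: macro
  (unweighted class means — sensitive to rare classes) and overall
  (sample-level accuracy with support-weighted P/R/F1). Pure
  micro-averaging would force Precision = Recall = Accuracy in the
  multiclass case, which cannot reproduce distinct overall metrics, so the
  support-weighted reading is used for the sample-level flavour. Undefined
  per-class metrics (zero support, or zero predicted positives) are
  reported `NA` and excluded from macro means with a warning rather than
  zero-filled.
* **Density-stratified evaluation** scores the sparse and dense test
  strata separately and reports their metric deltas, probing robustness to
  colony crowding; `run_ablation_grid()` trains every variant on every
  grouped fold of a shared split and reports fold mean ± sd.

## The synthetic data generator

The generator stands in for a private field campaign; it emulates its
statistical structure, not its photographs:

* **Images.** Procedural leaf backgrounds (multi-octave value noise plus
  vein-like line fields) carry elliptical targets with class-specific
  eccentricity, hue and micro-texture frequency. `"sparse"` images hold
  1–3 non-overlapping targets; `"dense"` images hold 5–8 overlapping ones
  in a cluster, partially covered by leaf-coloured foreground occluders —
  the aggregation-and-occlusion regime that degrades visual evidence in
  crowded colonies. Per-target pixel fractions are drawn from
  `target_scale_range` (default 1.2–2% of the frame; the lower end is
  bounded so a target spans at least ~2 pixels at the 16 x 16 desk
  resolution). A `target_contrast` of 0 renders targets invisible — the
  chance-level control.
* **Class structure.** Default per-class counts scale a 12,130-image
  field campaign's imbalanced proportions down to ~600 images. An optional
  `confusable_pair` renders two classes with identical visual parameters,
  so they are separable only through the environment channel.
* **Sensors.** One shared stream at a 10-minute period: diurnal sinusoids
  for temperature and humidity, a daylight illumination curve clipped to
  0 lux at night, Gaussian noise, and per-class mean shifts. With
  probability `outlier_rate` a record carries an extreme excursion on one
  channel (10–16x the channel's natural scale); each channel is missing
  with probability `missing_rate`. All injections are retained as ground
  truth so the cleaning steps can be validated by recall against them.
* **Group and time structure.** Each acquisition group covers one class,
  one density tag and one daily session window; records inside a session
  carry that group's class shift (the ecological premise that pest
  presence co-varies with microclimate — and the only construction that
  makes a single shared stream class-conditional). Image timestamps are
  jittered by up to `clock_jitter` seconds against the sensor clock.

What passing tests on this generator do **not** show about real data:
photorealism, within-class morphological diversity, multi-species plots,
non-stationary weather, sensor drift, or imaging-chain artefacts. The
generator supports *relative* statements — ablation orderings, leakage
guards, recovery of injected corruption — not absolute field accuracy.

## Desk-scale study conditions

The stochastic experiments in the test suite use: ~600 images rendered at
32 x 32 and resolution-normalized to 16 x 16 by the standard pipeline,
`scale_factor = width_factor = 1/4`, the relational unit off (its toggle
is part of the design), 8 epochs at batch 32, learning rate 3e-3 with the
fixed step decay, weight decay 1e-3 (without it the desk-scale model
memorizes its ~420 training images and fails to generalize across
acquisition groups), and a handful of seeds with dataset, split and
initialization all keyed to the seed. The chance-level control disables both the visual
signal (`target_contrast = 0`) *and* the environmental class shifts, since
either modality alone carries class information by construction.

## Known limitations

* Training at reference scale (64-channel level-1 maps, 2M parameters) is
  functional but slow in plain R; the package is designed for desk-scale
  studies and method validation, not production-scale training.
* The "w/o sensor prior" ablation keeps the collaborative head's sensor
  pathway by contract, so on strongly environment-determined synthetic
  data it can approach the full model; the gap between them is small and
  stochastic at desk scale.
* Boundary extrapolation of missing sensor values is nearest-value, a
  choice that biases long leading/trailing gaps toward their nearest
  observation.
* The grouped greedy splitter targets sample-count ratios, not class
  balance; with single-class groups (as the generator produces) rare
  classes can be absent from small partitions, which the metrics handle
  via undefined-markers.
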