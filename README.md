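# pestfusion

Image-level recognition of small-target crop pests (aphids, thrips,
whiteflies, leafhoppers, spider mites, leaf beetles) from **paired visual
and environmental-sensor data**, in plain R.

Small pests occupy a tiny fraction of image pixels, sit on cluttered leaf
textures, and their occurrence co-varies with instantaneous microclimate.
`pestfusion` implements a multi-scale vision–sensor collaborative
classifier together with everything around it: a synthetic multimodal data
generator, the preprocessing pipeline, group-aware splitting and
cross-validation, metrics in macro and sample-level flavours, a
density-stratified evaluation, and an ablation harness.

## The model

For an input image `X` (64×64×3 at reference scale) and a standardized
sensor vector `ŝ ∈ R³` (temperature °C, relative humidity %RH,
illumination lux):

1. **Feature pyramid.** A convolutional backbone (3×3 kernels, batch
   norm, ReLU; stride-2 stages) yields four levels `F⁽ˡ⁾` with spatial
   sizes 64/32/16/8 and channels 64/128/192/256; level 4 carries a
   global-context branch.
2. **Channel attention.** `w⁽ˡ⁾ = σ(W₂ δ(W₁ z⁽ˡ⁾))` from the pooled
   descriptor `z⁽ˡ⁾`; `F̂⁽ˡ⁾ = w⁽ˡ⁾ ⊙ F⁽ˡ⁾`.
3. **Cross-scale fusion.** `F_ms = Σ_l α_l · proj(F̂⁽ˡ⁾)` with learnable
   `α = softmax(logits)` (so `Σ α_l = 1` always), after 1×1 projection to
   256 channels and bilinear upsampling; a 3×3 relational unit refines the
   fused map.
4. **Environmental prior modulation (FiLM-style).** A 3→32→128 trunk with
   per-level sigmoid heads emits gates `g ∈ (0,1)^C`; channels are
   rescaled as `F̃_{h,w,c} = g_c F_{h,w,c}` (the level-4 head is the
   printed 128→256 mapping and also modulates the fused map).
5. **Collaborative head.** `u = ψ(W_b ψ(W_a ŝ))`; per-level conditional
   gates `c_i = P_i u + q_i` are broadcast and injected residually,
   `M_i = F̃_i + φ(F̃_i ⊙ G_i)`; levels are upsampled, concatenated (640
   channels), compressed to 256, pooled, and classified 256→128→6 with
   softmax.

Ablation variants (`no_multiscale`, `no_sensor_prior`, `no_collab_head`,
`concat_fusion`, `vision_only`) remove one mechanism each.

The network **and its reverse-mode differentiation are hand-implemented on
BLAS matrix operations** (im2col convolutions, a small autodiff tape, Adam)
— the package has no deep-learning framework dependency. `scale_factor`
and `width_factor` shrink the geometry for desk-scale experiments at
identical topology.

## Worked example

```r
library(pestfusion)

# 1. synthesize a multimodal field campaign (~600 images, 6 classes,
#    class-conditional microclimate, a visually confusable pair)
cfg <- synth_config(image_size = c(32, 32), confusable_pair = c(2, 3), seed = 101)
ds  <- generate_dataset(cfg)
ds
#> Synthetic multimodal pest dataset: 599 images (32 x 32), 6 classes
#>   groups: 48 | dense fraction: 0.37 | sensor records: 6913

# 2. preprocess: clean sensors, align, z-score (stats from training split)
pp   <- preprocess_config(h0 = 16, w0 = 16)
plan <- make_split(ds$groups, seed = 1)           # grouped 70/15/15
plan
#> Grouped split plan
#>   train   418 samples (69.8%), 32 groups
#>   val      83 samples (13.9%), 7 groups
#>   test    98 samples (16.4%), 9 groups
idx <- split(seq_along(ds$groups), plan$partition)
tr  <- prepare_samples(ds, pp, indices = idx$train)
ho  <- prepare_samples(ds, pp, stats = tr$stats, indices = c(idx$val, idx$test))

# 3. train the full model at desk scale (quarter spatial/width)
model <- build_variant("full", spec = pyramid_spec(1/4, 1/4),
                       relational = FALSE, seed = 1)
fit <- train_model(model, tr,
                   train_config(epochs = 8, batch_size = 32,
                                learning_rate = 3e-3, weight_decay = 1e-3,
                                seed = 1))

# 4. evaluate on the held-out groups
evaluate_model(fit, ho)
```

On this configuration the report prints (your machine will reproduce it
exactly — everything is seeded):

```
Evaluation report (n = 181)
  overall: acc 0.790 | prec 0.833 | rec 0.790 | F1 0.788
  macro:   acc 0.930 | prec 0.829 | rec 0.805 | F1 0.798
  support accuracy precision recall    f1
1      39    0.851     0.600  0.923 0.727
2      15    0.950     0.667  0.800 0.727
3      38    0.928     0.879  0.763 0.817
4      38    0.890     0.950  0.500 0.655
5      24    0.978     0.917  0.917 0.917
6      27    0.983     0.962  0.926 0.943
```

The fitted object prints its learned cross-scale fusion weights — always a
probability vector over the four pyramid levels:

```
summary(fit)
#> Fitted vision-sensor pest classifier (variant: full)
#>   epochs: 8 | final train loss 0.0376, acc 0.993
#>   parameters: 126,098
#>   fusion weights: 0.229 0.225 0.239 0.306 (sum 1.000000)
```

Overall metrics are sample-level (support-weighted); macro weights every
class equally, so rare classes pull it down — the two flavours answer
different questions. `density_stratified_eval(fit, ho)` contrasts sparse
vs dense (crowded, occluded) test imagery, and `run_ablation_grid()`
reproduces the component ablation table over grouped CV folds.

A YAML-driven command-line front end is installed with the package:

```sh
Rscript inst/cli/pestfusion generate --config config.yaml
Rscript inst/cli/pestfusion train    --config config.yaml --variant full
Rscript inst/cli/pestfusion ablate   --config config.yaml --folds 5
```

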