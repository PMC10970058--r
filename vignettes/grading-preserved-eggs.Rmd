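---
title: "Grading preserved eggs from candling images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading preserved eggs from candling images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peggnet)
```

## The problem

Preserved (century) eggs are sorted by shining a bright light through the
shell and reading the transmitted pattern. Five phenotypes matter in
practice: qualified eggs (QP) show a translucent reddish albumen and air
chamber with an opaque yolk; pale eggs (PP) are under-pickled and transmit
only a weak pale-yellow glow; broken-yolk eggs (BYP) show an irregular
yolk/albumen boundary; yellow-yolk eggs (YYP) show a yellow rim where the
yolk failed to darken; inferior eggs (IP) are spoiled and almost fully
opaque. For sorting, the three substandard phenotypes (PP, BYP, YYP)
collapse into one grade (SP), giving a three-grade task (QP/SP/IP) on top
of the five-class one. `peggnet` implements the classification models, the
loss, the data handling and the metrics for both tasks.

## Models

The feature extractor is a ConvNeXt: a 4×4 stride-4 convolutional stem,
four stages of residual blocks (7×7 depthwise convolution, channel layer
normalisation, a 1×1 expansion to 4C with GELU, a 1×1 projection back to
C, a learnable per-channel scale initialised at `1e-6`, and a
stochastic-depth residual add), with LN + 2×2 stride-2 downsamplers between
stages, and a global-average-pool → LN → linear head. Six dimensionings are
provided (`tiny` … `xlarge` plus the reduced `nano` with widths
[64, 128, 256, 512]); a block at width C contributes exactly `8C² + 58C`
parameters, which is what pins the per-variant totals:

```{r}
sapply(c("tiny", "small", "base", "large", "xlarge", "nano", "msff", "pegg"),
       function(v) count_params_variant(v)$formatted)
```

The grading network (`build_pegg()`) augments the nano backbone with:

* **Global attention (GAM)** on the stage-2 and stage-3 lateral maps:
  a channel gate (permute so channels trail, shared two-layer perceptron
  with a bottleneck, sigmoid) followed by a spatial gate (7×7 convolution
  to the bottleneck width, batch norm + ReLU, 7×7 back to C, sigmoid), each
  multiplying the map elementwise. Both preserve shape; with all weights
  zero each gate is exactly 0.5, so the composite collapses to `0.25·x` —
  a closed form the tests exploit.
* **Multi-scale feature fusion (MSFF)** in two steps: the stage-4 map
  (512 ch, S/32) is reduced to 256 channels by a 1×1 convolution,
  upsampled 2×, concatenated with the attended stage-3 map and refined by
  three ConvNeXt blocks at width 512; the result is reduced to 128
  channels, upsampled to S/8, concatenated with the attended stage-2 map
  (128 ch) and refined by three blocks at width 256. The head pools the
  final 256-channel map.

### Design choices where the architecture was open

Three points of the published description do not pin the design down, and
the parameter budget (20.6M without attention, 21.0M with it, versus 12.5M
for the bare nano backbone) is the only hard constraint; our choices are:

* **The second fusion scale.** A stage-2 map at "56 × 56 × 256" is
  inconsistent with both stride arithmetic (S/8 = 28 for a 224 input) and
  the stage-2 width (128). We fuse at S/8 and use the 128-channel stage-2
  map directly, making the second fused stream 256 wide. Together with the
  512-wide first fusion this reproduces 20.6M exactly; widening the second
  fusion to 512 would overshoot by ~5M.
* **The attention bottleneck.** The reduction ratio of the GAM perceptron
  and convolutions is unstated. A fixed bottleneck *width* of 8 channels at
  both placements (ratio 16 on 128 channels, 32 on 256) adds 308,032
  parameters — the only symmetric choice that lands the published 21.0M;
  a fixed *ratio* of 16 at both placements would add 513k and round to
  21.2M. `gam_config()` defaults to width 8 and remains overridable.
* **Upsampling** is bilinear (half-pixel centres), with nearest available;
  the choice does not affect parameter counts.

Block internals follow the original ConvNeXt design (expansion 4, GELU,
layer scale `1e-6`, channels-last LN); the printed parameter counts are
reproduced only under that design, which is how we validate it. The models
train from random initialisation (truncated normal, sd 0.02); there is no
pretrained-weight dependency, though `set_state()` accepts externally
produced weights with matching shapes.

## Loss

Training minimises `0.5·CE + 0.5·FL`: cross-entropy plus a focal term
`−α_t (1−p_t)^γ log p_t` that down-weights easy samples and re-weights
scarce classes. Since neither `α` nor `γ` is published, the defaults are
the focal-loss convention `γ = 2` and `α` proportional to inverse training
class frequency normalised to mean 1 (`alpha = "inverse_frequency"`);
both are configurable. Two numerical conventions to note: batch reduction
is the *mean* (the sum-over-batch form scales gradients with batch size),
and `log` arguments are clamped at `1e-12`. Setting `γ = 0, α ≡ 1` makes
the focal term equal cross-entropy exactly, a limit asserted in the tests.

## Data handling

Splitting is per class with the floor-floor-remainder rule —
`floor(0.7n)` train, `floor(0.2n)` validation, remainder test, after a
seeded within-class shuffle. This rule is adopted because it reproduces
the published split table exactly from the class totals
(692/332/523/323/257 → 1487/423/217):

```{r}
labels <- rep(egg_labels(), c(692, 332, 523, 323, 257))
split_table(labels, split_dataset(labels, split_spec(seed = 1)))
```

Augmentation expands the training set tenfold: copy 1 is the identity
(preserving the raw distribution), and each further copy applies
horizontal flip, vertical flip, rotation (uniform in ±30°, bilinear, black
fill — the background is black anyway), contrast and brightness scaling
(factors in [0.8, 1.2]) independently with probability 1/2 each. The
"each operator with probability 1/2" reading of a "random assortment" and
all ranges are package choices, configurable in `augment_spec()`; the
count arithmetic (1487 → 14,870) holds for any of them. Preprocessing
resizes the shorter side to 8/7 of the target, centre-crops, and
standardises with training-split channel statistics (candling images are
nothing like natural images, so no external statistics are used).

## The synthetic generator

No public dataset of candled preserved eggs exists, so
`generate_synthetic_dataset()` renders parametric scenes that reproduce
the *relative pixel statistics* separating the five phenotypes: a dark
box background (level 0.03), an elliptical silhouette with soft falloff, a
bright air-chamber cap, a class-conditional albumen colour (reddish for
QP/BYP/YYP, weak pale-yellow for PP, near-black for IP), an opaque yolk
disk whose boundary is a sum of angular harmonics (relative amplitude 0.16
for BYP against 0.02 otherwise), and a yellow annulus at the yolk rim for
YYP, plus Gaussian pixel noise (sd 0.015). Everything derives from one
seed, so a `(params, counts)` pair renders identical pixels on every call.

What the generator is *not*: a light-transport simulation. It has no
shell-thickness variation, no specularities, no pose/scale diversity
beyond mild jitter, and its class differences are cleaner than real
candling imagery. Tests that pass on it demonstrate that the pipeline is
wired correctly end to end (shapes, gradients, optimisation, metrics), not
that the model reaches any particular accuracy on real eggs — the
published real-data accuracies are out of reach without the original
private dataset.

## Metrics

`confusion()` builds the K×K matrix (rows true, columns predicted);
accuracy is trace/total — the standard multiclass reading of the binary
TP/TN form, equivalent to it at K = 2 — and precision/recall/F1 are
one-vs-rest. Metrics with an empty denominator return 0 with a warning
rather than erroring, so small synthetic evaluations never crash.
`consolidate_grades()` sums the PP/BYP/YYP rows and columns into SP;
because merging can only move off-diagonal mass onto the diagonal, grading
accuracy ≥ classification accuracy always — asserted on randomised
matrices in the tests. Reports round per-class F1 to one decimal in
percent.

## Training loop and problem sizes

`run_training()` uses AdamW (decoupled weight decay, skipped for biases,
normalisation gains and layer scales) with an optional cosine schedule,
evaluates on the validation split each epoch, and keeps the
best-validation checkpoint; history and manifest are written as JSON so a
run is reproducible from its manifest (one seed each for split,
augmentation and initialisation; evaluation-mode forward passes are
bitwise deterministic). The engine is plain R arrays plus an
im2col/BLAS convolution kernel in C++, so problem sizes are chosen for a
single CPU: the standard smoke test overfits the full 21.0M-parameter
grading network on 20 synthetic images at 32×32 (the network is fully
convolutional; any multiple of 32 works) to 100% training accuracy, which
takes roughly ten epochs with a constant learning rate of `1e-3`.
Stochastic depth defaults to 0 so unit tests are deterministic; 0.1 is a
reasonable training value.

```{r, eval = FALSE}
ds <- generate_synthetic_dataset(synthetic_egg_params(size = 32, seed = 7),
                                 c(QP = 4, PP = 4, BYP = 4, YYP = 4, IP = 4))
cfg <- train_config(variant = "pegg", epochs = 200, batch_size = 20,
                    lr = 1e-3, schedule = "constant", input_size = 32,
                    seeds = list(split = 1, augment = 1, init = 1))
fit <- run_training(cfg, ds, stop_at_train_acc = 1)
evaluate_checkpoint(fit$model, ds, model_name = "ConvNeXt_PEgg")
```

## Known limitations

* Training at 224×224 on thousands of images is possible but slow in this
  engine; it targets desk-scale verification, not production training.
* Batch-norm running statistics make a *training-mode* forward pass
  stateful (evaluation mode is pure); the training loop accounts for this.
* The synthetic classes are linearly separable by design; do not read
  synthetic accuracies as estimates of real-world performance.
* `load_image_folder()` reads PNG/JPEG via EBImage; 16-bit inputs are
  rescaled to [0, 1] by the reader.
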