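# peggnet

Internal-quality classification and grading of preserved (century) eggs
from transmitted-light (candling) images, in R.

Preserved-egg factories sort product by candling: a bright light behind the
egg reveals its interior as a translucency pattern. Five phenotypes are
distinguished — qualified (QP: translucent reddish albumen, opaque yolk),
pale (PP: weak pale-yellow glow), broken-yolk (BYP: ragged yolk/albumen
boundary), yellow-yolk (YYP: yellow rim at the yolk edge) and inferior
(IP: near-total opacity) — and for sorting, PP/BYP/YYP collapse into one
substandard grade (SP), giving a three-grade task on top of the five-class
one. `peggnet` provides the full pipeline for both tasks:

* **Backbones** — a configurable ConvNeXt feature extractor
  (`build_backbone()`) in the five standard sizes plus a reduced `nano`
  dimensioning with stage widths [64, 128, 256, 512]. Blocks are the
  standard design: 7×7 depthwise conv → channel LN → 1×1 expand ×4 → GELU
  → 1×1 project → layer scale → stochastic-depth residual.
* **The grading network** (`build_pegg()`) — `nano` trunk + global
  attention (sequential channel/spatial sigmoid gating, `build_gam()`) on
  the stage-2/3 lateral maps + a two-step multi-scale feature-fusion neck
  (1×1 reduction, 2× upsampling, concatenation, three ConvNeXt blocks per
  step) + a 5-way head. Exact trainable parameters: 20,955,653 (21.0M),
  a 24.5% reduction against the 27.8M tiny backbone.
* **Loss** — the hybrid objective `0.5·CE + 0.5·FL` with focal term
  `−α_t (1−p_t)^γ log p_t` for class imbalance (`loss_params()`,
  `combined_loss()`).
* **Data kit** — per-class 7:2:1 floor-rule splitting (`split_dataset()`),
  seeded tenfold augmentation (flips, rotation, brightness/contrast;
  `augment_training_set()`), directory-per-class IO
  (`load_image_folder()`), and a seeded synthetic candling-image generator
  (`generate_synthetic_dataset()`) emulating the five phenotypes so the
  whole pipeline is testable without proprietary imagery.
* **Evaluation** — confusion matrices, accuracy/precision/recall/F1, and
  5-class → 3-grade consolidation (`consolidate_grades()`), with report
  tables in the conventional per-class-F1 layout.
* **Training** — AdamW on the hybrid loss with per-epoch validation,
  best-checkpoint tracking and JSON history/manifest (`run_training()`,
  `evaluate_checkpoint()`). The network engine (convolution via
  im2col + BLAS in C++, normalisation, attention, backpropagation) is
  implemented in the package.

## Worked example

Overfit the full grading network on a tiny synthetic set — the standard
end-to-end smoke test (about a minute on one CPU):

```r
library(peggnet)

count_params_variant("pegg")$formatted
#> [1] "21.0M"

ds <- generate_synthetic_dataset(synthetic_egg_params(size = 32, seed = 7),
                                 c(QP = 4, PP = 4, BYP = 4, YYP = 4, IP = 4))
cfg <- train_config(variant = "pegg", epochs = 200, batch_size = 20,
                    lr = 1e-3, schedule = "constant", input_size = 32,
                    seeds = list(split = 1, augment = 1, init = 1))
fit <- run_training(cfg, ds, stop_at_train_acc = 1)
nrow(fit$history)   # epochs until 100% training accuracy
#> [1] 9

evaluate_checkpoint(fit$model, ds, model_name = "ConvNeXt_PEgg")
#> Classification (5 classes):
#>          Model Parameter QP Egg F1/% PP Egg F1/% BYP Egg F1/% YYP Egg F1/%
#>  ConvNeXt_PEgg     21.0M         100         100          100          100
#>  IP Egg F1/% Accuracy/%
#>          100        100
#>
#> Grading (3 grades):
#>          Model Parameter QP Egg F1/% SP Egg F1/% IP Egg F1/% Accuracy/%
#>  ConvNeXt_PEgg     21.0M         100         100         100        100
```

The first table is the five-class report (per-class F1 in percent plus
overall accuracy); the second is the consolidated three-grade report.
Grading accuracy is never below classification accuracy, since merging the
substandard classes can only turn confusions into correct grades. On this
deliberately separable synthetic set both reach 100% once the network has
memorised the 20 images; real candling imagery is far harder (the package
ships no real data, as none is public).

Dataset arithmetic for the published class totals:

```r
labels <- rep(egg_labels(), c(692, 332, 523, 323, 257))
split_table(labels, split_dataset(labels, split_spec(seed = 1)))
#>             QP  PP BYP YYP  IP Total
#> train      484 232 366 226 179  1487
#> validation 138  66 104  64  51   423
#> test        70  34  53  33  27   217
#> Total      692 332 523 323 257  2127
```

A command-line interface wrapping these functions ships at
`system.file("cli", "peggnet.R", package = "peggnet")` with subcommands
`generate-data`, `split`, `train`, `evaluate` and `count-params`.

## Method background

The model family and study design follow the published line of work on
non-destructive preserved-egg inspection with an improved ConvNeXt
(reduced feature dimensions, multi-scale feature fusion, global attention,
hybrid cross-entropy/focal loss). See the methods vignette
(`vignettes/grading-preserved-eggs.Rmd`) for the full model description,
the design decisions taken where the architecture was underdetermined, and
what the synthetic data does and does not establish.
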