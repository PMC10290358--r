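# reedcover

Estimating how much of a lake scene is covered by common reed
(*Phragmites australis*) from RGB aerial or drone imagery. Reed stands that
expand unchecked close over open water and degrade lake biodiversity, so
wardens and ecologists monitoring protected wetlands need a repeatable,
low-annotation way to quantify reed cover per scene. `reedcover` is aimed at
that use: it needs only *pure-class* photographs for training — images that
are entirely reed, and images of areas with no reed — never pixel-level
labels.

## The method

1. **Tiling.** Every photograph is cropped into small squares (default
   32×32 px) with an overlap of fifty percent both vertically and
   horizontally; a final flush window per axis guarantees full coverage.
   Each crop inherits its photograph's class label.
2. **Split.** All crops are randomly shuffled and split 70% / 30% into
   training and validation sets (`floor(0.7n + 0.5)` train tiles). A
   leakage-safe `group_by_source` mode that keeps whole photographs on one
   side is also provided.
3. **Classifier.** A compact CNN — two convolution layers (3×3, same
   padding, ReLU), two pooling layers (max or average, 2×2), one fully
   connected layer — ends in a two-unit softmax giving
   p(reed | tile) + p(non-reed | tile) = 1. Training runs 30 epochs of
   minibatch Adam on the categorical cross-entropy, logging per-epoch
   accuracy and loss on the validation partition. The network, including
   backpropagation, is implemented in base R (vectorised im2col
   convolutions); runs are single-threaded and bit-reproducible by seed.
4. **Evaluation.** Validation predictions are tallied into the 2×2
   confusion matrix (TP / FP / TN / FN, reed positive) with derived
   accuracy, precision, recall, specificity and F1.
5. **Coverage.** The trained classifier slides over a full scene with the
   same overlapping tiling; per-tile reed probabilities are averaged into a
   per-pixel probability field, thresholded (default 0.5, ties = reed) into
   a binary mask whose mean is the scene's **coverage fraction**, and
   optionally flagged against a configurable risk threshold.

A procedural generator of reed/water textures and composite scenes with
exact ground-truth masks stands in for drone photographs throughout the
tests, so the whole pipeline is verifiable offline. The package also ships
the reference chemistry of dry-reed samples (EDX elemental composition, and
pH / conductivity / soluble salts of aqueous reed extracts, with the
published analyte concentration ranges) plus the conductometric
cell-constant formula `k = (γ₁/c₁ + γ₂/c₂) / 2` used to calibrate
conductivity measurements against two KCl standards.

## Worked example

```r
library(reedcover)

# synthetic stand-in for pure-class field photographs
corpus <- make_training_corpus(n_per_class = 20, image_size = 64, seed = 0)
ds <- build_dataset(corpus$reed, corpus$non_reed, tile_size = 32)
print(ds)
#> Labelled tile set: 360 tiles of 32x32x3 (reed = 180, non_reed = 180)

fit <- reed_cnn(ds, seed = 1)   # 70/30 split + 30 epochs of Adam
summary(fit)
#> Reed/non-reed patch classifier
#>   architecture : conv(8, 3x3) -> max-pool(2) -> conv(16, 3x3) -> max-pool(2) -> fc(1024 -> 2) -> softmax
#>   tile size    : 32 px, 3 channels
#>   parameters   : 3442
#>   split        : 252 train / 108 validation ( tile_shuffle )
#>   training     : 30 epochs; val accuracy 1.0000, val loss 0.0000 (final epoch)

# a scene with known ground truth, then coverage recovery
scn <- compose_scene(scene_spec(256, 256, target_coverage = 0.4, seed = 7))
print(scn)
#> Synthetic scene 256x256 px, true reed coverage 0.3988
cov <- coverage_map(fit, scn$image)
print(cov)
#> Coverage map 256x256 px: reed coverage fraction 0.4141 (threshold 0.50, tile 32 px, mean mode)
print(risk_flag(cov, risk_threshold = 0.6, scene_id = "demo"))
#> Scene demo: coverage 0.4141 < risk threshold 0.60 -> not flagged

val <- subset_tiles(ds, fit$split$val_ids)
print(confusion_counts(val$meta$label, predict(fit, val, type = "class")))
#> Confusion matrix (positive = reed ):
#>        predicted
#> truth   reed other
#>   reed    55     0
#>   other    0    53
```

The fitted scene's recovered coverage (0.4141) sits within 0.016 of the
planted ground truth (0.3988); the residual comes from tiles straddling
reed/water boundaries. `plot(fit)` draws the loss and accuracy curves;
`write_checkpoint()` / `read_checkpoint()` persist the model as a
single-file JSON checkpoint.

The chemistry fixtures work the same way from R:

```r
range_summary(load_chem_table("extract"), "pH")
#>  min  max
#> 4.91 4.98
cell_constant(gamma1 = 2, c1 = 1, gamma2 = 1, c2 = 1)
#> [1] 1.5
```

## Command line

A thin CLI over the same functions lives at `inst/cli/reedcover.R`
(subcommands `simulate`, `tile`, `split`, `train`, `eval`, `covermap`,
`chem`; JSON config with flag overrides; every run writes a seeded
manifest beside its outputs):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "reedcover.R", package = "reedcover"))')" \
  train --seed 1 --output_dir runs/demo
```

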