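---
title: "Methods: patch-based convolutional mapping of reed cover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based convolutional mapping of reed cover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the modelling idea

Dense stands of common reed (*Phragmites australis*) expand aggressively
along lake margins; where they close over open water they reduce habitat
diversity, so monitoring programmes want a cheap, repeatable way to estimate
how much of a scene photographed from a drone is covered by reed.

`reedcover` implements a patch-classification approach. The training signal
comes from *pure-class* photographs — images that are entirely reed and
images of areas not covered by reed — so no pixel-level annotation is
needed. Each photograph is truncated into small squares with an overlap of
fifty percent both vertically and horizontally; every crop inherits its
photograph's label; the crops are shuffled and split 70/30 into training and
validation sets; and a compact convolutional network is trained for 30
epochs to tell the two classes apart. At inference time the same overlapping
tiling slides the classifier over a full scene, per-tile reed probabilities
are averaged into a per-pixel field, and thresholding the field yields a
binary reed mask whose mean is the scene's *coverage fraction*.

## The classifier

The network is deliberately small: two convolution layers, each followed by
a pooling layer, then one fully connected layer ending in a two-unit softmax
that emits a probability per target class,

$$p(\text{reed} \mid x) = \frac{e^{z_1}}{e^{z_1} + e^{z_2}},$$

with $z$ the fully-connected outputs. Training minimises the categorical
cross-entropy by minibatch Adam. Per epoch we record the mean training
loss, the validation loss (mean negative log probability of the true
class) and the validation accuracy (fraction of validation tiles whose
argmax class matches the label).

The forward and backward passes are written in base R as an im2col gather
plus one matrix product per convolution. On the corpus sizes this package
targets (hundreds of 32 px tiles) a 30-epoch run takes well under a minute
on one CPU core, and because everything is plain double arithmetic on a
single thread, runs are bit-reproducible given the seed.

### Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `tile_size` | 32 | px | large enough to contain several stem periods of texture, small enough that a modest corpus yields hundreds of crops |
| `overlap_fraction` | 0.5 | — | the protocol's fifty-percent overlap; also what makes stitched coverage maps smooth |
| `conv_channels` | (8, 16) | — | smallest widths that separate the two textures reliably; keeps the fit CPU-cheap |
| `kernel_size` | 3 | px | standard smallest receptive field; same padding preserves spatial size |
| `pooling` | max | — | both max and average are supported; max is the default because it responds to the brightest stripe within a window |
| `pool_size` | 2 | px | halves resolution twice, so `tile_size` must be divisible by 4 |
| `epochs` | 30 | — | the protocol's training length |
| `learning_rate` | 1e-3 | — | Adam's conventional default; stable at these batch sizes |
| `batch_size` | 32 | tiles | balances gradient noise against steps per epoch; corpora with fewer than ~100 training tiles learn faster with smaller batches (more Adam steps) |
| `threshold` | 0.5 | probability | mask cut on the stitched field; ties count as reed (`>=`) |
| `risk_threshold` | 0.6 | fraction | heuristic placeholder — no field-validated numeric rule for an "at-risk" scene exists, so this is exposed and documented as such |

Weight initialisation is a seeded uniform fan-in scheme,
$W \sim U(-1/\sqrt{f}, 1/\sqrt{f})$ with $f$ the fan-in, biases zero. It is
fixed (and documented here) purely for reproducibility; nothing downstream
depends on the particular scheme.

### The split and its leakage caveat

The default split shuffles *individual tiles*, which replicates the field
protocol but leaks information: two crops that overlap by half share pixels,
and they can land on opposite sides of the split. Validation accuracy under
`tile_shuffle` is therefore an optimistic estimate of photo-level
generalisation. The leakage-safe alternative `group_by_source` assigns whole
source images to one side; with it the train fraction can only be hit
approximately (whole images move at once). Both modes are deterministic
given the seed, and both are exercised by the test suite. The train size
under `tile_shuffle` is exactly `floor(0.7 * n + 0.5)` (round half up).

## Coverage mapping

A scene is tiled with the same fifty-percent overlap (the tiler appends one
extra flush window per axis when the last regular stride does not reach the
far edge — "shift-to-fit" — so no margin is left unmapped). Interior pixels
are covered by four windows at 50% overlap; each pixel's probability is the
unweighted arithmetic mean of the covering windows' reed probabilities.
Averaging before thresholding (rather than hard per-tile votes, available as
`mode = "vote"`) uses the overlap to smooth boundary estimates. The
coverage fraction is monotone non-increasing in the threshold by
construction, and the `>=` convention makes the tie behaviour explicit.

Boundary tiles that straddle a reed edge are the dominant error source:
their probability reflects a nonlinear mix of the two textures, so the
recovered fraction can deviate from truth by a few percent of scene area.
The error shrinks as the patch size grows relative to the tile size.

## The synthetic-scene generator

The generator replaces drone photographs for development and testing. It is
a *statistical caricature*, not a photorealistic renderer:

* **reed** — a vertically striated anisotropic pattern: a sinusoid across
  columns (default period 5 px) with slow per-row phase drift, per-stem
  brightness variation, a green-brown palette, and seeded Gaussian noise;
* **water** — a smooth low-frequency field: bilinear interpolation of a
  coarse Gaussian grid (one cell per ~16 px), a blue-grey palette, and the
  same noise.

The two classes differ in mean colour (green-minus-blue is positive for
reed, negative for water) and in anisotropy. Anisotropy is measured as the
ratio of mean squared luminance increments along x to those along y
(`axis_variance_ratio`); increments are preferred over variances of
row/column means because the ratio then averages over all H×W pixel pairs
and concentrates tightly, making the isotropy band for water statistically
stable. Reed ratios exceed 1.5 and water ratios stay within [0.67, 1.5] for
at least 99 of 100 seeds, and a fixed linear probe on mean colour separates
the classes with ≥ 99% accuracy — together these guarantee the training
problem is well posed before any network is involved.

Scenes are composed by placing random axis-aligned ellipses and rectangles
of reed on a water background until the mask mean is within 0.02 of the
target coverage; each candidate patch's area is drawn at 50–100% of the
remaining deficit so the loop converges geometrically and cannot overshoot.
A pixel belongs to a patch iff the patch covers the pixel centre. The
recorded `true_coverage` is the exact mean of the final mask, so
ground-truth consistency is exact by construction. What the generator does
**not** emulate: perspective and scale variation, seasonal spectral change,
sun glint, mixed vegetation, sensor noise models. Passing tests on
synthetic scenes therefore demonstrate that the pipeline's geometry,
training loop and coverage arithmetic are correct — not that the classifier
would transfer to field imagery without retraining on real photographs.

### Problem sizes used in the shipped checks

The default study corpus is 20+20 source images of 64×64 px, tiled at 32 px
with 50% overlap into 360 tiles (252 train / 108 validation); coverage
recovery is checked on 256×256 px scenes at planted fractions 0.2, 0.4 and
0.6. These sizes were chosen as the smallest at which the texture statistics
are stable and training converges comfortably within the 30-epoch schedule.

## Numerical choices and degenerate inputs

* Stride is `round(tile_size * (1 - overlap))`; a stride below 1 px or a
  raster smaller than the tile is an error, not a silent clamp.
* Softmax subtracts the row maximum before exponentiation; evaluation clamps
  probabilities at 1e-12 before the log, so a saturated correct prediction
  reports loss 0 rather than NaN, while a non-finite *training* loss aborts
  with the epoch index.
* Undefined confusion-matrix ratios (0/0) are reported as missing (`NA`),
  never coerced to 0, so degenerate validation sets cannot inflate a metric.
* Pooling ties under `max` resolve to the first window element
  (deterministic); `argmax` class ties resolve to reed, consistent with the
  `>=` mask convention.
* Checkpoints are JSON with a versioned header: the architecture spec
  round-trips exactly; parameters are stored in full decimal precision and
  reproduce to within double rounding (relative error < 1e-12).

## Design choices that were genuinely open

* **Tile size** is never stated by the field protocol ("small squares");
  32 px is the default and everything is parameterised over it.
* **Stitching** uses the unweighted mean over covering windows — the
  simplest rule that is exact for uniform inputs; distance-weighted schemes
  were rejected as unjustifiable without ground truth to calibrate against.
* **Two-unit softmax head** rather than a single sigmoid logit, mirroring
  the per-class probability formulation of the protocol.
* **Round-half-up** for the 70% train size, fixing the protocol's
  percentages to an exact integer rule.
* **Risk flagging** is an explicit placeholder (`>=` on a configurable
  coverage threshold, default 0.6): the ecological literature gives no
  numeric criterion for when reed coverage becomes a biodiversity risk.

## Known limitations

* The synthetic textures are easy by design; real reed/water separability
  will be worse, and the validation accuracy shown on synthetic corpora
  should not be quoted as expected field accuracy.
* `tile_shuffle` leaks between partitions (see above); use
  `group_by_source` when estimating generalisation.
* The coverage map has tile-scale resolution: features narrower than half a
  tile are blurred into their surroundings.
* No georeferencing: coverage is a fraction of pixels, not hectares.
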