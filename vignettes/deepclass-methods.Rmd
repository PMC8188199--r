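---
title: "deepclass: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{deepclass: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

deepclass is a headless, scriptable workbench for training convolutional
and multilayer-perceptron classifiers on labeled biological image
collections — microscopy tiles, imaging-flow-cytometry event crops,
or any folder of class-labeled PNGs/TIFFs/JPEGs. This vignette explains
the models and procedures it implements, the parameters that matter, the
synthetic data the test suite runs on, and the design decisions taken
where conventions were genuinely open.

## The uniform dataset container

Every stage consumes one container: `N` images of identical geometry
(`N x H x W x C`, 8-bit intensities 0–255 before normalization), integer
labels `0..K-1`, class names, per-image source identifiers, and a split
tag (`train`/`valid`/`test`). Ingestion paths are a
one-subdirectory-per-class image folder (`load_folder()`) and a canonical
HDF5 layout (`images` uint8 dataset, `labels` vector, class names as root
attributes). The HDF5 file can be loaded into RAM (`read_imageset_h5()`)
or opened disk-backed (`open_imageset_h5()`), and both access paths
expose the identical contract (`get_images()`, `n_images()`,
`image_geometry()`), so training code never knows where pixels live; the
disk-backed path streams per batch for datasets larger than memory.

Conventions used throughout: arrays are row-major with origin at the
top-left, indices in the public tile interfaces are 0-based, and tile
intervals are half-open (`[r*s, (r+1)*s)`).

## Geometry and intensity preprocessing

**Color.** RGB→gray uses the luminosity method,
`gray = 0.21 R + 0.72 G + 0.07 B`, weighting green most because the eye
is most sensitive to it. Outputs are rounded half-up and clipped to
`[0, 255]`; round-half-up (rather than R's round-half-even) was chosen so
the mapping is monotone in each channel and matches 8-bit storage of
other toolchains. Gray→RGB stacks three identical channels; because the
weights sum to 1, the round trip is the identity.

**Scaling.** `scale_image()` maps a side of `n` pixels to
`floor(n * factor)` (so 28 px × 1.15 → 32 px, the enlargement used to
feed 28-pixel images into a 32-pixel input layer). Four separable
resampling kernels are provided — nearest neighbor, linear, quadratic,
cubic — implemented as 1-D interpolation matrices with center-aligned
coordinates (`src = (i + 0.5)/f − 0.5`), Lagrange weights for the
3- and 4-point kernels, and edge clamping. Weights sum to 1 in every
row, so a constant image stays constant and factor 1 is exactly the
identity.

**Crop/pad.** `equalize_size()` center-crops or zero-pads to a square
target. Odd remainders go to the trailing (bottom/right) side — an
arbitrary but documented convention that makes the operation
deterministic and idempotent. Pad fill is 0. Rectangular inputs are
handled per axis (crop the long axis, pad the short one) under
`scale_then_equalize`; the strict `center_crop`/`pad` modes refuse
inputs on the wrong side of the target and point to the other mode.

**Normalization.** Three methods: `div255` (to `[0, 1]`);
`dataset_standard`, standardizing by the mean and SD of *all pixels of
the training split* (population moments, `1/n`); and
`per_image_standard`. The dataset statistics are fitted once with
`fit_normalizer()` on the training split and frozen into the spec, so
validation and test data are transformed with training statistics only —
the usual leakage guard. A constant image under per-image
standardization maps to all zeros (SD treated as 1, with a warning)
rather than dividing by zero. `mean_sd()`, used for summarizing
per-image accuracies for reporting, deliberately uses the *sample*
(n−1) SD — the reporting convention — while pixel standardization uses
population moments; the two conventions serve different purposes and
are pinned by separate tests.

## The augmentation engine

`augment_batch()` applies a fixed operator chain: horizontal/vertical
flips (each fires with probability 1/2 per image when enabled) →
rotation (angle uniform in ±`rotation_max` degrees) → integer shift
(uniform in ±`shift_max` pixels per axis) → zoom (scale uniform in
`1 ± zoom_delta`) → additive brightness (uniform in
±`brightness_add_max` intensity units) → multiplicative brightness
(uniform in `brightness_mult_range`) → Gaussian noise (per-image SD
uniform in `[0, noise_scale_max]`, then i.i.d. per pixel) → one final
round/clip to 8-bit → center crop to the model's input side.

Design choices worth knowing:

* **Crop last.** Batches should arrive at a slightly larger working
  size; cropping after rotation avoids the black-wedge edge artifacts
  that cropping first would rotate into view.
* **Brightness before normalization.** All brightness arithmetic acts on
  raw 0–255 intensities; normalization happens afterwards in the
  training loop.
* **One clip.** Intermediate stages may leave `[0, 255]`; values are
  rounded and clipped once, after the noise stage. Clipping per stage
  would bias the noise distribution at the rails.
* **Nearest-neighbor resampling, zero fill** for rotation/shift/zoom —
  consistent with the 8-bit integer pipeline and cheap.
* **Zoom "±0.35"** is read as a multiplicative scale uniform in
  `[0.65, 1.35]`.
* **Determinism.** Every draw derives from `(config$seed, batch_index)`
  through a local RNG that restores the caller's stream; identical
  inputs give bit-identical outputs across processes, which is what
  makes full training runs replayable.

`preset_config("cifar_gray")` and `preset_config("fashion_mnist")`
return the two published parameter sets (rotation ±5° / ±10°, 1-pixel
shifts, brightness add ±15, multipliers 0.6–1.4 / 0.7–1.3, noise scale
≤10 / ≤5). The presets enable the horizontal flip only; both flags exist
on the config.

## The model zoo and the training engine

There is no deep-learning runtime underneath: the engine is a compact
vectorized R implementation of stride-1 im2col convolution, 2×2 max
pooling, dense layers, inverted dropout, softmax cross-entropy with
per-class weights, and SGD with momentum (0.9 by default). The backward
pass is verified against numerical differentiation in the test suite.
This keeps the package dependency-free and fully deterministic, at the
cost of raw speed — it is intended for desk-scale experiments
(thousands of small images), not ImageNet.

Built-in architectures (`build_model(name, input_side, channels,
n_classes)`):

* `lenet5` — 2 convolutional (5×5, 6/16 filters, valid padding) +
  3 dense layers (120/84/K); 61,706 parameters at 32×32×1, K = 10.
* `nitta_6layer` — 4 convolutional (3×3 same, 32/32/64/64) + 2 dense
  layers (256/K).
* `resnet_6conv` — 6 convolutional layers (32→128 filters) with identity
  residual connections around each conv pair (skips apply when channel
  counts match) + 4 dense layers (256/128/64/K).
* `mlp_128`, `mlp_128_64` — plain MLPs.

Exact filter widths for the deeper nets are package choices recorded in
each model's `ModelSpec`, so tests pin them. The registry is extensible:
`register_architecture()` makes a new constructor buildable by name.
Weights are initialized He-normal (Glorot for the output layer) from a
named seed, which the provenance machinery records.

**Training** (`train_model()`) runs per epoch: poll the control source →
draw a balanced per-class sample (`n_per_class` with replacement for
undersized classes) or a full shuffle → augment, normalize, and fit
minibatches → evaluate the full, un-augmented validation split → keep
the checkpoint with the best validation accuracy so far. Class-weighted
cross-entropy is the loss; `make_class_weights()` offers uniform,
inverse-frequency (`N/(K·N_k)`), and manual coefficients. The optimizer,
batch size, and loss are package defaults, documented as such.

**Live hyper-parameter control.** The control source — a YAML file
re-read before every epoch, or an epoch-keyed schedule list — may change
the learning rate, dropout rate, per-class sample size, class weights,
or any augmentation field mid-run. Polling is epoch-granular by design:
it is the scriptable equivalent of adjusting sliders during training
while keeping runs bit-reproducible. Every applied change is logged as
an event and snapshotted per epoch in the history.

**Provenance.** `write_meta()` writes a YAML meta-file with the software
version, master seed, model architecture + init seed, SHA-1 content
fingerprints of both datasets, the full starting configuration, all
change events, and per-epoch snapshots. `rerun_from_meta()` verifies the
fingerprints, rebuilds the model, replays the events at their original
epochs, and reproduces the original history exactly. Checkpoints carry
optimizer state, so resumed training continues identically.

**Transfer learning.** `set_trainable()` freezes/unfreezes individual
parameterized layers; frozen layers are skipped by the optimizer and
remain bit-identical. `plateau_unfreeze()` mechanizes gradual
unfreezing: when the best validation accuracy of the last `patience`
epochs beats the best of all earlier epochs by less than `epsilon`, the
deepest still-frozen layer (closest to the output) is proposed next.
The defaults (`patience = 5`, `epsilon = 0.005`) are pragmatic choices;
the decision rule itself is the documented contract.

## Evaluation

`evaluate_model()` produces the full report: K×K confusion matrix (rows
true, columns predicted), per-class precision/recall/F1/support,
accuracy, one-vs-rest ROC and precision–recall curves with trapezoidal
AUCs, and the raw probability matrix. Curve points sit at every distinct
predicted probability (ties grouped), predictions counted as positive at
`score >= threshold`; the PR curve is anchored at recall 0 with the
precision of the strictest threshold. Division-by-zero cases (a class
never predicted or absent) yield metric 0 plus a `zero_division` flag
rather than NaN. For binary tasks the positive-class AUCs are exposed
directly. `confusion_cell_examples()` returns the source ids behind any
confusion cell — the data structure behind an interactive confusion
matrix. All metrics are tested to 1e−9 against a brute-force counting
oracle, and ROC-AUC additionally against pROC.

`threshold_purity()` implements the probability-histogram analysis for
binary classifiers: events with positive-class probability strictly
above `upper` are called positive, strictly below `lower` negative, the
band between stays unassigned, and each called stratum reports the
fraction of calls that are truly the called class. Strict inequalities
were chosen (boundary events stay unassigned); an empty stratum is
reported as undefined (`NA`), never as 0.

## The tile pipeline

Segmentation-as-classification for stained-culture micrographs: an
expert marks differentiated pixels (stored as a pure-green RGB (0,255,0)
overlay; `decode_mask()` matches exactly, near-green does not match),
the image is partitioned into disjoint square tiles
(`floor(H/s) × floor(W/s)`, residual borders discarded with a warning;
a 320×320 image at s = 32 gives exactly 100 tiles), and each tile is
labeled class 1 iff it contains ≥ `min_marked` marked pixels (default
5). The threshold adopts the stricter of the two printed conventions
(≥5, equivalently "more than four") and is exposed as a parameter.

Grid partitioning leaves class 1 heavily under-represented, so
`oversample_positive_tiles()` draws extra tiles at uniformly random
fully-inside offsets, keeping those meeting the ≥5-pixel criterion
(rejection sampling, budget 1000 attempts per requested tile) — this
balances the classes *and* presents stained structures at varied
positions, aiding translation invariance. `build_tile_dataset()`
composes both sources and keeps per-tile provenance
(`source@row0:col0`) recoverable via `parse_tile_ids()`. Tiles inherit
the imageset normalization pipeline; masks are never normalized.
`predict_tile_map()` reconstructs the per-image grid of argmax classes
with class-1 probabilities, and `per_image_accuracy()` scores grid
agreement against the mask-derived truth, summarized across images as
mean ± SD.

## Synthetic fixtures: what they emulate and what they do not

The generators make the whole pipeline testable without external data;
all are pure functions of their seed.

* `make_shapes_dataset()` — up to six shape families (disk, square,
  cross, ring, bar, triangle) with position (±2 px), size (0.27–0.31 of
  the side), and intensity (190–215) jitter over a noisy background
  (SD 6). The jitter is deliberately mild so that even a raw-pixel
  nearest-centroid baseline separates the easiest pairs (>0.9) — this
  guarantees the CNN learning-sanity test is passable by construction,
  which is its purpose.
* `make_stained_culture()` — 320×320 RGB images with a per-image warm
  background tint (120–220, with an illumination gradient) and reddish
  elliptical blobs; the mask is exactly the blob-pixel union. It
  emulates the dominant nuisance of real stained cultures — strong
  image-to-image variation in background color and staining density —
  but not texture, cell morphology, focus gradients, or ambiguous
  expert labels.
* `make_cell_events()` — single-cell crops in which each event is a
  disk with Gaussian area and Gaussian interior brightness per
  population, mirroring the area × brightness scatter used to gate
  blood-cell populations. Populations whose ±1 SD boxes overlap
  trigger a warning because rectangular gating would mislabel. The
  model is deliberately minimal: no deformation physics, no
  fluorescence, no rare-population modeling.

Because the fixtures are cleanly separable by construction, passing the
learning-sanity tests demonstrates that the training loop, gradients,
sampling, and bookkeeping work — not that any particular accuracy would
be reached on real micrographs or cytometry data.

## Numerical choices and degenerate inputs

* Pooling requires even feature-map sides; incompatible input sides are
  rejected at construction with the minimal working side named.
* Max-pool ties resolve to the first window position; ROC ties are
  grouped at distinct probability values with trapezoidal integration.
* Softmax subtracts the column maximum before exponentiation;
  cross-entropy clamps probabilities at 1e−12.
* Empty strata, empty masks, zero-member classes, constant images, and
  unparseable control files all have defined behavior (error, warning +
  fallback, or flagged NA) exercised by tests.
* Problem sizes in the test suite and acceptance script (800/200 shape
  images, 8 + 2 synthetic cultures, ≤8 epochs) were chosen as the
  smallest scales at which the learning-sanity properties hold robustly
  across seeds on a single CPU.

## Known limitations

* No GPU, no compiled backend: wall-clock scales linearly with pixels ×
  filters; practical up to tens of thousands of small images.
* ONNX or other cross-framework export is not implemented; the native
  serialized checkpoint is the supported exchange format, and
  `export_model()` names the supported list when asked for anything
  else.
* Only square model inputs are supported (rectangular data are
  equalized per axis first).
* The residual architecture applies identity skips only where channel
  counts match; no projection shortcuts.
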