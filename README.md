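# deepclass

Headless deep-learning image classification for microscopy and imaging
flow cytometry, in R.

Many image-classification problems in the life sciences — grading
stained cell cultures, counting blood-cell populations from
imaging-flow-cytometry frames, sorting event crops into phenotypes —
are bottlenecked not by exotic architectures but by workflow: getting
heterogeneous labeled images into one container, augmenting and
balancing them sensibly, training with full provenance so a run can be
reproduced months later, and reporting the metrics reviewers expect.
deepclass packages that workflow as a scriptable R library plus a thin
command-line entry point, with no GUI and no external deep-learning
runtime: the CNN/MLP engine (im2col convolution, max pooling, dense
layers, dropout, class-weighted softmax cross-entropy, SGD with
momentum) is implemented in vectorized R and verified against numerical
gradients.

What it covers:

* **Dataset assembly** — one-folder-per-class image trees (PNG/TIFF/JPEG)
  or a canonical HDF5 container; RAM-resident and disk-streamed access
  behind one contract; luminosity RGB↔gray conversion
  (`0.21R + 0.72G + 0.07B`); scaling with nearest/linear/quadratic/cubic
  kernels; center-crop/pad size equalization; `div255`, dataset-, and
  per-image standardization fitted on the training split only.
* **Augmentation** — flips, rotation, integer shifts, zoom, additive and
  multiplicative brightness, Gaussian noise, in a fixed order with the
  final center crop after rotation; bit-reproducible per
  `(seed, batch index)`; published presets (`cifar_gray`,
  `fashion_mnist`).
* **Training** — per-epoch balanced class sampling (the antidote to
  erythrocyte-dominated datasets), class-weighted loss, validation after
  every epoch with best-checkpoint keeping, *live* hyper-parameter
  updates from a control file polled between epochs, and an automatic
  YAML meta-file (data fingerprints, every change event, per-epoch
  snapshots) from which `rerun_from_meta()` reproduces a run exactly.
* **Transfer learning** — per-layer freezing (`set_trainable()`) and a
  plateau rule for gradual unfreezing (`plateau_unfreeze()`).
* **Evaluation** — confusion matrix with per-cell example drill-down,
  precision/recall/F1/support, ROC and PR curves with AUCs,
  probability-threshold purity analysis for binary tasks, CSV/JSON
  export.
* **Tile pipeline** — segmentation-as-classification for stained
  cultures: pixel masks from pure-green overlays, 32×32 tiling with the
  ≥5-marked-pixel labeling rule, positive-tile oversampling at random
  locations, per-image tile maps and accuracies.
* **Synthetic fixtures** — shape classes, stained-culture images with
  ground-truth masks, and two-feature (area × brightness) cell-event
  populations with rectangular gating, so everything above is testable
  end to end without external data.

## Worked example

Train LeNet-5 on a synthetic 4-class shape dataset and evaluate it:

```r
library(deepclass)

tr <- make_shapes_dataset(4, 100, 32, seed = 1, split = "train")
va <- make_shapes_dataset(4, 25, 32, seed = 2, split = "valid")
tr
#> <image_set> 400 images, 32x32x1, 4 classes, split 'train'
#>   disk square  cross   ring
#>    100    100    100    100

model <- build_model("lenet5", 32, 1, 4, seed = 1)
model
#> <dl_model> lenet5: 32x32x1 -> 4 classes, 5 parameterized layers, 61,196 parameters

res <- train_model(model, tr, va,
  training_config(epochs = 4, batch_size = 32, learning_rate = 0.02,
                  seed = 3), verbose = TRUE)
#> epoch 1: acc 0.4950 val_acc 0.9600
#> epoch 2: acc 0.9025 val_acc 0.8900
#> epoch 3: acc 0.8775 val_acc 0.9900
#> epoch 4: acc 0.9925 val_acc 1.0000

evaluate_model(res$model, va)
#> <evaluation_report> 100 samples, accuracy 1.0000
#>         predicted
#> true     disk square cross ring
#>   disk     25      0     0    0
#>   square    0     25     0    0
#>   cross     0      0    25    0
#>   ring      0      0     0   25
```

`acc` is the training-batch accuracy of each epoch (computed on
augmented samples), `val_acc` the accuracy on the full, un-augmented
validation split; the checkpoint with the best `val_acc` is what
`res$model` returns. The evaluation report also carries per-class
precision/recall/F1/support and one-vs-rest ROC/PR curves.

The same run is scriptable from a shell via the CLI wrapper
(`inst/cli/deepclass.R`) with a YAML config whose `task` field selects
`synth`, `train`, `evaluate`, `tilepipe`, or `export`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "deepclass.R", package = "deepclass"))')" \
  --config run.yaml --seed 1
```

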