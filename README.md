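# boundseg

Boundary-aware loss functions and evaluation for binary medical-image
segmentation, at desk scale.

Small, bright lesions on textured backgrounds — the typical breast-tumor MRI
setting — break the usual segmentation objectives twice over: the
foreground/background imbalance starves the loss of foreground signal, and
overlap measures like Dice or IoU are indifferent to *where* the boundary
lands, although boundary shape (smooth versus spiculated margins) is what
later benign/malignant assessment depends on. `boundseg` implements the
**focal boundary Dice** compound loss

    L_seg = λ1·L_Dice(S, G) + λ2·L_Focal(S_e, G_e) + λ3·L_BD(S, Φ_G),
    λ = (0.5, 0.3, 0.2)

combining soft Dice overlap, an α-balanced focal loss on an edge head, and a
level-set boundary loss `mean(Φ_G · S)` driven by the exact signed Euclidean
distance map Φ_G of the target boundary (negative inside). Alongside it, for
controlled comparison, the package provides three alternative loss families
(weighted BCE + weighted IoU, BCE-based boundary, and a shape-aware loss
with compactness `P²/(4πA + o)` and contrastive smoothness terms), all with
analytic gradients.

Around the losses:

* **geometry** — inner-boundary extraction, exact Euclidean distance maps,
  signed level-set maps (`extract_boundary`, `distance_map`,
  `signed_distance`);
* **metrics** — Dice, precision, specificity, IoU/mIoU, pixel accuracy and
  the max-form Hausdorff distance, per case and aggregated
  (`evaluate_case`, `evaluate_batch`, `write_report`);
* **preprocess** — tumor-quadrant cropping, Gaussian blur, CLAHE, min–max
  normalization, seeded elastic deformation and photometric/geometric
  jitter (`quadrant_split`, `augment_pair`, …), plus programmatic edge
  ground truth (`edge_ground_truth`);
* **synthetic data** — a seeded generator of MRI-like lesion images with
  smooth or spiculated margins and paired edge masks (`generate_sample`,
  `generate_dataset`, `shape_features`);
* **model** — a small deeply supervised encoder–decoder with a boundary
  attention module (edge-probability gating of decoder features) and
  hand-derived backpropagation, with training, k-fold cross-validation,
  loss-comparison and MLP shape-classification drivers (`build_model`,
  `train`, `cross_validate`, `compare_losses`, `classify_shapes`).

A thin command-line wrapper with `generate`, `augment`, `train`, `evaluate`,
`compare-losses`, `cross-validate` and `classify` subcommands is installed at
`inst/cli/boundseg`.

## Worked example

```r
library(boundseg)

# 200 synthetic 64x64 lesions, ~31%/69% train/test split
ds <- generate_dataset(200, smooth_fraction = 0.5, size = 64, seed = 101)
sp <- split_dataset(ds, seed = 101)

model <- build_model(model_config(seed = 1))
res <- train(model, sp$train, sp$test,
             loss_config("focal_boundary_dice"), epochs = 30, seed = 1)

te <- res$record[res$record$split == "test", ]
tail(te[, c("epoch", "loss", "dice", "miou", "pa", "hausdorff")], 1)
#>    epoch      loss      dice      miou        pa hausdorff
#> 62    30 0.7742213 0.9635452 0.9641909 0.9971853  1.613001
```

After 30 epochs the held-out Dice is 0.964 (1.0 would be pixel-perfect
overlap), class-averaged mIoU 0.964, pixel accuracy 0.997, and the mean
Hausdorff distance — the largest boundary deviation, in pixels — is 1.6,
i.e. predicted boundaries sit within about two pixels of the truth. The
`record` data frame holds the full per-epoch curves for both splits.

Shape classification from the resulting masks:

```r
cls <- classify_shapes(ds$samples, seed = 1)
round(unlist(cls[c("accuracy", "sensitivity", "specificity")]), 3)
#>    accuracy sensitivity specificity
#>           1           1           1
```

The generator's smooth/spiculated margin semantics are strong enough that
the four shape features separate the classes essentially perfectly — by
design, so that boundary quality is a recoverable signal in tests.

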