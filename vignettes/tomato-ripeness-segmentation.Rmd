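---
title: "Convolutional-transformer segmentation of tomato ripeness: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convolutional-transformer segmentation of tomato ripeness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomaformer)
```

# The problem

Greenhouse tomatoes are graded by ripeness before harvest. The grading rule
is colorimetric: a fruit is *fully ripe* when at least 90% of its surface is
red, *half ripe* when 30–89% is red, and *unripe* below 30%. In imagery, the
task is dense: every pixel of an RGB scene must be assigned to background or
to one of the three ripeness classes, under foliage occlusion, heavy class
imbalance (unripe fruit dominates by an order of magnitude) and variable
lighting. `tomaformer` implements a hybrid convolutional-transformer
segmentation network for this task, together with the synthetic data,
augmentation, loss, metric and training machinery around it. All forward and
backward passes are written in base R; there is no external deep-learning
runtime.

# The model

The network has four parts, configured by `model_config()` and built by
`build_model()`.

**Convolutional encoder.** Five levels (E-1..E-5), each holding two or three
*shape-preservation blocks* (SPBs) followed by one *residual block* (RB) —
11 SPBs and 5 RBs in total, three to four blocks per level. An SPB keeps
spatial resolution and applies exactly 4 convolutions, 4 batch
normalisations and 2 ReLUs: a main path conv–BN–ReLU–conv–BN, a projection
shortcut conv–BN, an elementwise sum, a ReLU, and a trailing conv–BN. An RB
applies 3 convolutions, 3 BNs and 2 ReLUs in the same residual arrangement
and ends in 2×2 stride-2 max pooling whose per-window argmax indices are
stored. After five levels the latent features `f_e` sit at 1/32 of the input
resolution; the pre-pool activation of each level is kept as a skip feature.
Kernels are 3×3 (1×1 for the projection shortcuts); default widths are
16/32/64/128/256 with a `width_multiplier` for small models.

**Transformer branch.** The input image is partitioned into `n_p`
non-overlapping square patches of side `P = sqrt(R*C/n_p)` (row-major grid;
`P` must divide both image dimensions). Each flattened patch is linearly
projected to width `l` and added to a learned positional embedding, giving
the token sequence `q^o`. Three transformer encoders are cascaded; each one
normalises the tokens, applies contextual multi-head self-attention
(`A_j = softmax(Q_j K_j' / sqrt(l)) V_j` per head, heads concatenated and
merged back to width `l`), adds the token residual, normalises again,
applies a linear–ReLU–linear feedforward and adds the normalised sum as a
second residual. The last encoder's output `p_t` is the branch's product.
Note the attention scaling uses `sqrt(l)` — the full embedding width — not
the per-head width; this is a deliberate, contract-tested choice.

**Fusion.** `p_t` is arranged on its patch grid, bilinearly resized to the
spatial dims of `f_e`, linearly projected to `f_e`'s channel width, and
multiplied elementwise into `f_e`, so the transformer projections act as a
multiplicative filter on the convolutional features; a 3×3 convolution then
yields the fused features `f_d`. The fusion mechanism is the package's
concrete realisation of "convolving `f_e` with `p_t`": it is shape-sound,
differentiable, and lets the projections literally gate the latent features.
A channel-concatenation alternative is available via
`model_config(fusion = "concat")`. Building with `use_transformer = FALSE`
drops the branch and the fusion stage entirely (the fully convolutional
ablation variant) and feeds `f_e` straight to the decoder.

**Decoder.** Five mirror stages: max-unpooling routed by the stored RB
indices (each pooled maximum returns to its recorded coordinate, zeros
elsewhere), elementwise addition of the matching encoder skip feature, and a
rescaling unit of convolution, batch normalisation and ReLU. A final 1×1
convolution produces per-pixel logits over the four classes; a softmax gives
the probability map at full input resolution. The decoder deliberately uses
five index-routed unpooling stages — one per encoder max-pool — since
argmax-routed unpooling is only well-defined where a pooling produced
indices; this mirror-symmetric layout is the package's resolution of the
otherwise underdetermined decoder depth, and skip fusion is by addition.

# The objective

Training minimises `L_t = beta1 * L_s1 + beta2 * L_s2` (`loss_config()`):

* `L_s1` — soft Dice: per sample, `1 - 2*sum(T*p) / sum(T^2 + p^2)`, sums
  running jointly over all pixels and classes, averaged over the batch. It
  is bounded in [0, 1] (AM–GM) and drives region overlap.
* `L_s2` — temperature-softened cross-entropy on `p = softmax(logits/tau)`.

Both terms consume the *same* temperature-softened probabilities: the
temperature `tau` softens the class distribution inside the Dice term as
well as the cross-entropy, which is the literal reading of the objective's
shared probability map. Defaults `beta1 = 0.9`, `beta2 = 0.1` (the weights
are constrained to sum to 1) and `tau = 1.5` are the grid-search optima of
the underlying method.

Two normalisation conventions needed fixing for dense prediction. The Dice
ratio is scale-free by construction. The cross-entropy, written
classification-style with one class-sum per sample, is averaged over pixels
as well as the batch here: each pixel is a sample of the per-pixel
classification task. This keeps the single-pixel anchor exact (uniform
logits over four classes give `log 4`) and makes loss magnitudes comparable
across image sizes. Numerically, predicted probabilities are clamped at
1e-12 inside the logarithm, and an all-empty Dice denominator (possible only
for a degenerate zero-pixel sample) returns 0 for that sample. Batch-norm
and layer-norm use epsilon 1e-5; analytic gradients of `L_t` are verified
against central finite differences in the test suite.

# Synthetic scenes

No public imagery ships with the package, and the generator
(`generate_scene()`, `generate_dataset()`) is a first-class module rather
than a test fixture. It emulates the *statistical* structure of greenhouse
ripeness data, not its appearance:

* **Ripeness by red fraction.** Each tomato is a disc whose surface is split
  into a red cap and green remainder matching a sampled red fraction; the
  class label follows the closed-boundary rule (`>= 0.90` fully ripe,
  `>= 0.30` half ripe) implemented in
  `ripeness_class_from_red_fraction()`.
* **Class imbalance.** The default `class_mix` normalises the instance
  counts 3557/196/724 (unripe/half/fully), i.e. roughly 79/4/16% — the
  documented imbalance of the emulated greenhouse dataset.
* **Occlusion.** Foliage ellipses are drawn *after* the tomatoes and
  relabel covered pixels as background, so instances are genuinely
  truncated; `occlusion_density` (default 0.15) is the target canvas
  fraction covered.
* **Lighting.** A multiplicative gain drawn from `lighting_gain_range`
  (default 0.7–1.3) varies scene brightness.

Per-scene tomato count (2–6) and radius (4–9 px on the default 64×64
canvas) are free parameters of the generator chosen at desk scale; the
540×640 published input size is supported by the same code. By default
discs are placed without touching one another, which gives the generator a
useful property: on occlusion-free scenes the per-class connected components
of the mask coincide exactly with the generated instances, so the instancing
and mAP machinery can be validated end-to-end against known ground truth.
What the generator does *not* emulate — specular highlights, stems, soft
shadows, texture — limits what passing tests say about real imagery: they
establish correctness of the machinery, not field performance.

The default test canvas is 64×64 and the test-suite models use width
multipliers of 0.25–0.5; these sizes were chosen so the whole verification
suite, including a 200-step training run, completes in minutes on one CPU
core while exercising every architectural element at full depth.

# Training and evaluation

`train()` optimises `L_t` with ADADELTA at its published defaults (learning
rate 1.00, accumulation/decay rho 0.95; conditioning epsilon 1e-6), batch
size 16 and 200 epochs by default, on a seed-deterministic 75/25
train/heldout split (`split_dataset()`). The heldout part serves both
validation and testing; after every epoch the model is evaluated on it and
the best-by-validation-mIoU parameters are checkpointed alongside the final
ones (best-mIoU selection is the package's choice of model-selection
criterion). Logs are JSON lines flushed per epoch. A published schedule of
512 iterations per epoch exceeds what a ~700-image dataset at batch 16
provides (~33 batches); `iterations_per_epoch` therefore defaults to the
dataset-determined count, with the larger value available as explicit
oversampling.

`evaluate()` aggregates, over a dataset:

* **Classwise IoU / Dice** from the pooled confusion matrix, averaged over
  the three tomato classes (background excluded, matching how the scores
  are reported for this task); classes absent from prediction and truth are
  excluded from the mean.
* **Mask-derived bounding-box mAP.** The method is semantic, but detection
  scores are computed directly from masks: 8-connected components of each
  class support become instances; each yields the minimum bounding
  rectangle of its occupied rows/columns, scored by the mean predicted
  class probability over the component. Predictions are greedily matched
  one-to-one to ground-truth components at box-IoU ≥ 0.5 (threshold
  config-exposed), and AP is the all-point-interpolated area under the
  precision–recall curve. Connectivity (8 vs 4), the 0.5 threshold and
  all-point interpolation are the package's resolutions of otherwise open
  protocol choices; each is oracle-tested.
* **Pixel AUC**: one-vs-rest ROC AUC of each tomato class's probability
  over all pixels (rank statistic, ties at 1/2), macro-averaged over the
  classes present — the package's concrete definition of the reported AUC.

# Augmentation

`apply_augmentation()` / `augment_dataset()` implement brightness, blur,
horizontal/vertical flips, rotation, horizontal/vertical shear, salt &
pepper, speckle and zoom. Geometric ops warp image and mask with identical
geometry — bilinear for the image, nearest-neighbour for the mask (labels
are categorical; interpolation must never invent a label) — and fill exposed
regions with background. Photometric and noise ops leave the mask
bit-identical. Default magnitudes (rotation ±30°, shear ±15°, zoom 0.8–1.2,
brightness ±25%, salt-pepper rate 0.02, speckle variance 0.05, blur σ = 1)
are package choices, config-exposed. The ambiguous "vertical variation"
transform is implemented as a vertical flip. Scenes containing the minority
half-ripe class can be oversampled.

# Known limitations

* Pure-R training is desk-scale: overfitting one 64×64 scene (200 steps)
  takes about two minutes on one core; training a full-width model on
  hundreds of 540×640 images is out of reach without a compiled backend.
* The generator's parametric scenes cannot support claims about real
  greenhouse imagery; they validate machinery, not field accuracy.
* Internal details of some encoder variants referenced by the underlying
  method (identity blocks, hierarchical decomposition blocks, the
  "butterfly" topology) are not specified anywhere and are deliberately not
  implemented; the five-level SPB/RB encoder is authoritative here. For the
  same reason published parameter totals (~52M) are not reproducible and no
  attempt is made to match them.
* Whether the cascaded transformer encoders share weights is unspecified;
  the package uses independent weights per encoder, and learned (not
  sinusoidal) positional embeddings.

# A worked check

```{r, eval = FALSE}
sc <- generate_scene(scene_config(seed = 11))
cfg <- train_config(
  epochs = 10, batch_size = 1, iterations_per_epoch = 20, seed = 3,
  model = model_config(input_size = c(64, 64), width_multiplier = 0.5,
                       transformer = list(width = 32, heads = 2,
                                          ff_width = 64, patch_size = 8)))
res <- train(list(list(image = sc$image, mask = sc$mask)), cfg,
             validation = NULL, auto_split = FALSE)
tail(res$log$train_loss, 1)   # ~0.006 after 200 steps
f <- model_forward(res$last, sc$image)
iou_and_dice(confusion_matrix(f$mask, sc$mask))$mean_iou  # ~1.0
```

The same computation, together with the generator's class-mix check and the
generator-vs-metrics mAP self-consistency, is what `scripts/acceptance.R`
re-runs from scratch.
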