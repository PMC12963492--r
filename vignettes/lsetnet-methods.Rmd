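---
title: "LSeTNet: model, pipeline, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LSeTNet: model, pipeline, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

`lsetnet` implements a lightweight hybrid image classifier for medicinal-plant
leaf disease diagnosis across twelve classes (three species — *Kalanchoe
pinnata*, *Azadirachta indica* (neem), *Ocimum tenuiflorum* (tulsi) — each
with one healthy and three disorder phenotypes such as web blight, leaf spot,
chlorosis, downy mildew). The architecture combines three ideas:

1. **A lightweight convolutional backbone.** A 3×3 stem (64 channels) and
   three residual blocks double the channel width (64→128→256→512) while 2×2
   max pooling with floor division halves the spatial grid:
   248 → 124 → 62 → 31 → 15 → 7.
2. **Squeeze-and-excitation (SE) channel attention.** Each block's main path
   output is recalibrated channel-wise: a spatial global average ("squeeze"),
   a two-layer bottleneck (reduction ratio 16, ReLU then sigmoid,
   "excitation"), and a per-channel gate in (0, 1). The residual update is
   `Y = MaxPool(phi(X) + SE(F(X)))`, where `F` is two conv–BN–ReLU layers and
   `phi` is an identity or a 1×1 conv + BN projection when the channel count
   changes.
3. **A single transformer encoder block on the 7×7 grid.** The 7×7×512 map is
   flattened row-major into 49 tokens of width 512; multi-head self-attention
   (`softmax(QK'/sqrt(d_k))V`, 8 heads, biases on all four projections) and a
   512-wide feed-forward layer are applied in post-norm residual form
   (`LayerNorm(x + Sublayer(x))`, two affine LayerNorms).

Global average pooling and a dense head (512 → 1024 ReLU → dropout → 12-way
softmax) produce the class probabilities. Training minimizes categorical
cross-entropy.

### Parameter accounting

`count_parameters()` reports per-stage counts; `lsetnet_budget_check()`
compares them against the published per-stage budgets. Five quantities are
internally consistent and treated as hard constraints, and the built model
reproduces them exactly:

| quantity | count |
|---|---|
| stem convolution (3×3×3→64 + bias) | 1,792 |
| first SE stage (64 ch, ratio 16)   | 580 |
| transformer block                  | 1,577,984 |
| dense head                         | 537,612 |
| non-trainable (BN running stats)   | 6,528 |

The published per-stage approximations for the residual blocks do not sum to
the published total, so those rows are soft: the check reports the deviation
without failing. Notably, the layout chosen here — forced by the consistent
budgets and the batch-norm accounting (ten BN layers over channels
64, 128×3, 256×3, 512×3, 512) — reproduces the published *totals* exactly:
9,387,688 parameters (35.81 MB float32), 9,381,160 trainable and 6,528
non-trainable. The "extra conv block" between the third residual block and
the transformer is implemented as conv–BN–ReLU + SE + pool; no standard
single- or double-conv layout reconciles its published per-stage
approximation, and the deviation is reported.

Design points that the budgets force: the SE reduction ratio is 16 everywhere
(the 580-parameter budget at 64 channels requires a hidden width of 4); the
transformer feed-forward width is 512 (not the common 4×), with biases and
exactly two LayerNorms; the head count (and the budget) is independent of the
attention head count, which defaults to 8. No positional encoding is used —
the architecture description never introduces one; a learned additive
embedding is available behind a configuration flag. The head dropout rate is
unstated upstream and defaults to 0.5 (dropout carries no parameters, so
budgets are unaffected).

## Preprocessing

Images are resized (plain bilinear, half-pixel centers) to 248×248, then
enhanced in a fixed order: CLAHE on the L channel of LAB space (clip limit
4.0, 12×12 tile grid; delegated to `EBImage::clahe`, whose tile grid requires
tile-divisible dimensions — the L channel is reflect-padded to the next
multiple and cropped back, so 248×248 works with the 12×12 grid), 9×9
Gaussian blur with
σ = 2, and unsharp masking `out = clip((1+α)·img − α·blur7(img))` with
α = 1.8. Resizing precedes enhancement so the CLAHE tile geometry is fixed
across inputs. The σ of the 7×7 unsharp blur is not stated upstream; the
package uses the standard kernel-size convention `σ = 0.3·((k−1)/2 − 1) + 0.8`
and exposes it in `preproc_config()`. The enhancement chain maps valid 8-bit
RGB to valid 8-bit RGB; the final standardization `x' = (x − μ)/σ` is the
only unbounded step, and its per-channel statistics are fitted from the
**training split only** (`fit_channel_stats()` aborts on any non-training
record). Whether those statistics should be computed before or after
augmentation is not specified upstream; they are fitted on preprocessed,
un-augmented training originals here, because augmentation operates in
photometric units and should see the same scale as the originals.

## Leakage-free splitting and augmentation

The dataset is split **before** augmentation: within each class, originals
are shuffled by a seeded RNG and assigned 70/15/15 (floor for validation and
test, remainder to train). Augmentation then expands each (class, split) cell
to its quota — 700/150/150 by default, 1,000 images per class — by composing
three randomly parameterized transforms per sample (rotation ±40°, scale
0.7–1.3, flips, ±60 px translation, brightness 0.6–1.5, contrast 1.5–2.3,
hue ±40° on the 0–360° circle, center zoom 1.4–1.8; reflection padding on
all geometric operations). Each augmented record carries its parent's id and
stays in the parent's split by construction; `audit_leakage()` verifies split
disjointness, parent-split consistency, and quota satisfaction. Because the
quota counts are the auditable quantity, the package materializes augmented
PNGs on request but also supports an on-the-fly mode in which augmented
records store only a derived seed and are synthesized at load time — both
modes produce identical counts and identical pixels for the same seed.

Cross-validation folds (`kfold_plan()`) are stratified by class and assign
whole augmentation families as a unit, so an original and its augmented
children never straddle a fold boundary. This is deliberately stricter than
a plain stratified fold: folds drawn from augmented data would otherwise
leak near-duplicates. Fold sizes are exactly equal whenever family sizes
permit; with 20 training originals per class expanded to 700 (families of
35), five folds hold exactly 140 records per class (1,680 in total),
matching the reference protocol's fold support.

## Training

Adam (β₁ = 0.9, β₂ = 0.999), batch size 32, up to 50 epochs. The learning
rate starts at 1e-3 and step-decays to exactly 1e-4; only the endpoints are
pinned upstream, so the default multiplies by 10^(−1/3) every 15 epochs
(three steps across 50 epochs) and hits both. Early stopping monitors
validation macro-F1 (maximized) with patience 10 and restores the best
epoch's weights; the monitor is configurable to validation loss, since the
source describes both variants in different places and the Methods statement
(F1-based) was preferred. No label smoothing, weight decay, or gradient
clipping. All randomness — split shuffles, initialization, mini-batch order,
dropout, augmentation parameters — derives from the run seed (default 42).

The network engine itself (convolution via im2col + GEMM in compiled code,
batch norm, SE, attention, layer norm, pooling, and their backward passes)
is part of the package; its gradients are verified against central finite
differences in the test suite, which is the engine's primary correctness
oracle.

## Explainability

**Grad-CAM** uses the pre-softmax logit of the target class; channel weights
are the spatially averaged gradients at the target stage and the map is the
rectified weighted activation sum, max-normalized per image (an all-zero map
stays zero). The default target layer is the 7×7 output of the extra
convolutional block — the last convolutional map before the transformer; the
reshaped transformer output is available as an alternative. The reported
intensity statistics are the map mean and the mean of its top 5% pixels; the
per-image max normalization convention is an assumption recorded here, since
the upstream convention is unstated.

**LIME** segments the image SLIC-style (k-means over pixel coordinates and
Lab color with a locality weight, ~100 segments by default), samples binary
masks, replaces absent segments by their mean color, weights masks by
`exp(−D²/0.25²)` with cosine distance to the full mask, and fits a
ridge-penalized weighted linear surrogate; the five largest-weight segments
and the surrogate's weighted R² are reported. Segment count, kernel width,
ridge strength, and sample count are not specified upstream; all are
configurable arguments with the defaults above. With the ridge at zero and
full mask enumeration the surrogate recovers a mask-linear black box exactly
(tested).

**t-SNE** embeds the GAP-layer features. No t-SNE implementation is
available among the installed packages, so the package carries the exact
O(N²) algorithm: per-point bandwidth calibration to the target perplexity
(30 by default), early exaggeration (×12 for 100 iterations), and
momentum gradient descent on `KL(P‖Q)`. It is intended for the
hundreds-of-points scale used here, not for large datasets. Cluster
statistics (per-class centroid, per-axis spread) and the Euclidean
silhouette on the 2-D coordinates accompany the embedding.

## The synthetic-leaf generator

Real leaf photographs cannot ship with the package, so every stage is
exercised on a deterministic procedural generator of the twelve classes.
Species differ in silhouette (broad scalloped Kalanchoe, serrated lanceolate
neem, small ovate tulsi), base hue, and vein pattern; disorders overlay brown
ringed spots, gray web filaments (with or without necrotic patches), uniform
chlorosis with or without green veins, marginal necrosis, angular mildew
patches with a gray-purple coating, or yellow halo rings. Pose varies by
±25° rotation and ±8% translation, with background clutter and lighting
jitter. Color bands are reserved so that leaf, background, and overlay
pixels remain separable by rule, which `class_signature_report()` exploits
to verify the classes are statistically distinct.

The signatures are deliberately exaggerated relative to real pathology, and
the generator does not model specular highlights, occlusion, focus blur, or
inter-class ambiguity. Passing tests on this data therefore demonstrate that
the pipeline is implemented correctly — counts, leakage freedom,
convergence, attribution arithmetic — not that the architecture reaches any
particular accuracy on real leaves; the published real-data accuracies
require the original datasets and GPU-scale training and are out of scope.

## Problem sizes and numerical choices

The test suite trains a width-reduced network (stem width 16, channels
16/32/64/128, 64×64 inputs, 256-wide head) on 80 generated images per class,
split 70/15/15 — the scale a reviewer can re-run on one CPU core in a few
minutes; it reaches ≥ 0.95 held-out accuracy well before its epoch budget.
Count-based checks use 28 originals per class, which the floor rule splits
20/4/4 so that the 700/150/150 quotas and exactly balanced folds of 1,680
are both attainable. Degenerate inputs are handled explicitly: a class with
fewer than three images aborts the split; a (class, split) cell above quota
aborts rather than discarding originals; zero-variance channels floor σ at
1e-6; ties in max pooling take the first maximum (fixed scan order), and
midranks are used for ties in AUC and the Friedman test. Batch norm uses
ε = 1e-5 and momentum 0.1 on the running statistics; evaluation mode uses
the running statistics, training mode the batch statistics.

## Known limitations

- The engine is CPU-bound, single-threaded R + BLAS; full-size training at
  248×248 is possible but slow, and the package is tuned for desk-scale
  experiments and architectural analysis.
- The on-the-fly augmentation mode re-synthesizes augmented pixels at load
  time; it is bit-identical to materialization but costs CPU at each load.
- The exact internal structure of the published "extra conv block" cannot be
  reconciled with its published approximate parameter count; the
  implementation reports its deviation and reproduces the published total.
- t-SNE is exact (quadratic); embedding more than a few thousand points is
  impractical.
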