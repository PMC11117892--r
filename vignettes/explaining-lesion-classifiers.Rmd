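---
title: "Explaining lesion classifiers through cancer characteristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explaining lesion classifiers through cancer characteristics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

camlink connects two views of a breast-ultrasound lesion classifier: the
pixel view (class-activation heatmaps) and the clinical view (the lesion
descriptors radiologists actually use — calcification, echogenicity
pattern, shape, margin). This vignette is the package's account of the
methods, the choices behind them, and what the synthetic test bed does and
does not demonstrate.

## The pipeline

1. **RoI preparation.** The annotated lesion boundary defines an
   axis-aligned bounding box, enlarged by 8% of each side (half per side,
   rounded outward) so the crop includes the tumor microenvironment, then
   resized to the classifier input with bicubic interpolation. The
   annotation is remapped into the resized frame (translate, scale, round
   to the nearest pixel), so all region masks live in classifier
   coordinates.
2. **Classification.** Any backend implementing the four-generic contract
   (`forward_with_features()`, `class_score_gradients()`,
   `score_with_ablated_map()`, `input_shape()`/`n_classes()`) can be used.
   The bundled `build_tiny_cnn()` is a from-scratch network; nothing is
   downloaded.
3. **Heatmaps.** EGrad-CAM or Ablation-CAM on the designated (last
   convolutional) layer, always for the *predicted* class — the point is to
   explain the decision actually made, including the wrong ones.
4. **Region scoring.** Per characteristic, the fraction of region pixels
   whose normalized heatmap score reaches 0.5 (the midpoint of the
   normalized scale) is the significant ratio `Rs`; outcome-stratified
   means `AvRs` are graded No / Very Low / Low / Medium / High.
5. **Faithfulness.** Explanation maps (top 80% of heatmap-ranked pixels,
   multiplied into the image) probe whether the heatmap marks pixels the
   model truly relies on: average confidence drop, percent increase in
   confidence, and win% between methods.

## Model assumptions

Both CAM methods assume the designated layer's feature maps are spatially
aligned with the input (true for convolutional stacks) and that a linear
readout of globally pooled activations produces the class score. The tiny
CNN makes that structure literal: 3×3 convolutions with ReLU, 2×2 max
pooling between blocks, global average pooling over the last activation,
and a linear two-class head. Two consequences are used as test oracles:

* ablating map *k* changes the pre-softmax score by exactly
  `w_ck * mean(F_k)`, and
* the score gradient with respect to the designated activation is the
  constant `w_ck / (h_f * w_f)`,

so the ablation scores and gradients have closed forms that an independent
re-implementation can check to machine precision.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `margin_fraction` | 0.08 | RoI bounding-box enlargement (fraction of each side; dimensionless) |
| `size` (RoI) | 224 for generic use; 32 for the bundled CNN | classifier input (pixels) |
| `gate`, `p` | `top_mass`, 0.95 | entropy gating: keep entropy-descending maps holding 95% of total entropy |
| `threshold` | 0.5 | significance cut on the normalized heatmap scale |
| category bounds | 0 / 0.2 / 0.35 / 0.5 | AvRs grading; Medium is open and High closed at 0.5 |
| `width_fraction` | 0.02 | ribbon half-width as a fraction of the mean bounding-box side |
| `top_fraction` | 0.8 | pixels retained in explanation maps (by count, ranked by score) |
| `epochs`, `lr`, `batch_size` | 30, 5e-3, 8 | tiny-CNN training (Adam) |

The 0.5 significance threshold is the midpoint of the normalized score
range; the grading bounds are fixed constants of the contribution scale.
The "top 95%" gate is read as *cumulative entropy mass* — maps are ranked
by entropy and kept until 95% of the total is covered, never keeping
zero-entropy maps — because this reading lets a large fraction of maps be
frozen when information is concentrated in a few, which is the behavior the
gating exists to exploit. A per-map `positive` (H > 0) mode and ungated
`all` mode are available for comparison, and every heatmap records which
rule produced it.

## The classifier backend

The spirit of the harness is transfer learning-scale explainability at desk
scale, so the bundled network is deliberately small (default: three blocks,
8 maps, 32×32 input, ~6k parameters). Two training choices depart from
what larger fine-tuned models would use. Max pooling, not average pooling,
sits between blocks: the malignancy evidence in the synthetic task includes
few-pixel bright calcification flecks, and average pooling attenuates such
small structures so strongly that global average pooling can no longer see
them. The Adam learning rate defaults to 5e-3: rates around 1e-4 are
appropriate for *fine-tuning* pretrained backbones, but training this tiny
network from scratch at that rate does not reach a useful optimum within a
desk-scale epoch budget. With the defaults, seed 1, and 200 training /
50 held-out synthetic images, training reaches ≥ 90% training accuracy
within 30 epochs and > 80% held-out accuracy; optimization at this scale is
seed-sensitive, so those figures are properties of the documented
configuration rather than of every seed. For unattended runs,
`train_backend(..., restarts = k)` trains `k` deterministic
re-initializations and keeps the one with the best *training* accuracy —
model selection that never touches held-out data; the acceptance script
uses three restarts.

## Region geometry

* **Interior (echogenicity):** even-odd rasterization over pixel centers,
  boundary pixels included. On convex polygons of ≥ 500 px the mask area
  tracks the shoelace area within 2%.
* **Calcification:** union of 3×3 windows centered at each annotated point,
  clipped at the image border. A per-window variant (score each window,
  then average) is available behind
  `calcification_scoring = "per_window"`; the union reading is the default.
* **Ribbon (shape/margin):** with `ARwh` the mean of the bounding box's
  width and height, half-width `w = max(1, round(0.02 * ARwh))`; the ribbon
  is the interior dilated by a radius-`w` disk minus the interior eroded by
  the same disk, i.e. inner and outer bands with the true boundary
  centered. Morphology with an explicit disk element
  `{(dr,dc): dr² + dc² ≤ w²}` was chosen over polygon offsetting because
  annotated lesion contours frequently carry small sharp angles that make
  offset curves self-intersect; the floor of 1 px keeps tiny lesions
  analyzable. Shape and margin share this geometry and differ only in the
  grouping label — the package deliberately does not attempt to separate
  them geometrically.

## Numerical conventions

* Resampling uses half-pixel-center alignment; bicubic is the Keys
  a = −0.5 kernel with clamping to [0, 255] (bicubic overshoots), heatmap
  upsampling is bilinear (raw CAM maps are low-resolution and nonnegative).
* Feature-map entropy quantizes each map by min–max scaling to [0, 255]
  and rounding; a constant map has zero range and is defined to carry
  0 bits.
* Heatmap normalization is min–max to [0, 1] *after* upsampling; an
  all-zero or constant raw map normalizes to all-zero (no discriminative
  signal), never to all-one.
* Ablation importance is undefined at `S_c = 0`; scores with magnitude
  below 1e-8 raise an error rather than returning an arbitrary value.
* An entropy gate that keeps no maps yields an all-zero heatmap with a
  warning, not an error — downstream statistics then correctly report "No"
  contribution.
* Empty outcome groups are reported as absent (`NA`, printed `-`), keeping
  "zero contribution with cases present" distinguishable from "no cases".
* Ties: explanation-map ranking breaks score ties by pixel index; max-pool
  gradients route to the first slice attaining the max. Both choices are
  arbitrary but fixed, which the byte-level determinism tests rely on.
* Outcomes use malignant as the positive class: TN = correct benign,
  TP = correct malignant, FP = benign predicted malignant, FN = malignant
  predicted benign. This convention is stated here once and used
  everywhere.

## The synthetic test bed

`generate_dataset()` emulates exactly the image features the analysis keys
on: multiplicative speckle (smoothed exponential noise), a hypoechoic
lesion bounded by a 64-vertex star-shaped polar curve whose harmonic
amplitude controls the shape label, bright Gaussian flecks at recorded
calcification points, low-frequency interior patches for non-uniform
echogenicity, and Gaussian edge blur for non-circumscribed margins. The
default class rule — malignant iff the boundary is irregular (amplitude
≥ 0.15) or at least one calcification is planted — gives planted-saliency
tests a causal basis: a heatmap that is hot exactly on the calcification
region *must* be graded High there and No on the disjoint boundary ribbon,
and the `oracle_backend()` produces such heatmaps directly from the ground
truth, bypassing any learned model.

What passing these tests shows: the geometry, bookkeeping and statistics of
the pipeline are correct, end to end, at machine precision where closed
forms exist. What it does not show: that the framework's conclusions
transfer to clinical ultrasound. The generator reproduces neither real
speckle statistics (no point-spread physics), nor posterior acoustic
features, orientation descriptors, rib shadows, or annotation noise; real
lesion boundaries are not star-shaped; and a 6k-parameter CNN is not a
transfer-learned deep backbone. Conclusions about *which* characteristics
drive *which* model must be re-derived on real data with a real backend —
the package provides the instrumentation, not the clinical result.

## Problem sizes

The test suite trains on 200 synthetic images (50 held out) and runs the
planted-saliency recovery on 100 images at a 64×64 RoI; the acceptance
script uses 120 training and 80 analysis images at 32×32 with 30 epochs.
These sizes were chosen as the smallest at which the classifier is clearly
better than chance and every outcome group is populated, keeping full runs
in the minutes range on one CPU core.

## Known limitations

* The backend contract is single-image; there is no batched inference, so
  very large datasets are slow by construction.
* `score_with_ablated_map()` re-runs the full forward pass per map; for a
  K-map layer Ablation-CAM costs K + 1 forwards.
* The ribbon's bounding rectangle is axis-aligned (consistent with the RoI
  crop); a rotated minimum-area rectangle would change `ARwh` slightly for
  oblong, tilted lesions.
* Faithfulness metrics inherit the brittleness of confidence-based probes:
  multiplying an image by heatmap weights darkens it globally, and a small
  network may lose confidence for reasons unrelated to localization. The
  metrics are comparative (method A vs B on the same model), not absolute.
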