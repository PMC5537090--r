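---
title: "Automated bone age assessment: models, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated bone age assessment: models, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(autobaa)
```

## The problem

Skeletal maturity ("bone age") is read from a left hand/wrist radiograph
by comparing ossification features — most importantly the progressive
closure of the growth plates (physes) — against reference standards.
`autobaa` implements a fully automated assessment pipeline: radiographs
are normalized, the hand is segmented by a patch-classification network,
the segmented image is standardized by a vision pipeline, and a
convolutional classifier assigns one of the 14 one-year bone-age classes
(5–18 years, one model per sex). Occlusion-sensitivity maps show which
image regions the classifier relies on, and a structured report carries
the prediction, three to five ranked reference suggestions and the
maturity stage.

## Pipeline stages and their models

### Grayscale-base and size normalization

Radiographs arrive with either polarity (bright bones on a dark
background or the inverse) and at native resolutions from a few hundred
to a few thousand pixels. The polarity test averages the pixel means of
the four 10×10 corner patches and inverts the image when that average
exceeds half the dynamic-range maximum (128 at 8 bits; the threshold is
`2^bits/2` exactly). The four corners are averaged — rather than voted
individually — because a single corner can hold a side marker. The
image is then rescaled (bilinear) so its larger dimension is 512 px and
zero-padded symmetrically to 512×512. Landscape inputs, rare in
practice, scale by their larger dimension; padding is 0 because a black
background has been established first.

### Patch detection network

Every pixel belongs to one of five classes: bone, tissue, background,
collimation, annotation marker. The detector is a LeNet-5-style network
— two convolution + max-pool blocks (6 and 16 channels, 5×5 kernels)
and two fully connected layers (120 hidden units, 5 outputs) — trained
on square patches whose label is the ground-truth class of the patch's
center pixel (at 0-based offset `floor(S/2)`). Patch sampling is
balanced exactly: `n_per_class` patches per class, without replacement
until a class pool is exhausted. Training uses SGD (momentum 0.9, base
learning rate 0.01 decreased tenfold at three evenly spaced epoch
boundaries — the published schedule gives the factor and the number of
steps but not their positions, so even spacing at ⌊E/4⌋, ⌊E/2⌋, ⌊3E/4⌋
is used); 25% of patches per class are held out and the
best-by-validation-accuracy epoch snapshot is returned, ties resolved
toward the later (more converged) epoch.

### Sliding-window label map

The detector slides across the 512×512 image with top-left corners at
multiples of the stride (default 4, patch 32 — the optimum of the
patch-size/stride sweep harness). Every pixel accumulates the **mean**
of the score vectors of all patches covering it, and takes the argmax
class; ties break toward the earlier class in the fixed order
bone < tissue < background < collimation < annotation. Mean-of-covering
votes is the natural aggregation — it reduces to the single patch score
when stride equals patch size. Border pixels not covered by any patch
inherit the nearest covered pixel's label (index clamping).

When the stride is a multiple of 4 (the product of the two 2× pooling
stages) the whole sliding window is computed in one fully convolutional
pass: conv/pool stages run once over the full image and the fully
connected layers act as convolutions on the pooled feature map. This is
numerically identical to scoring each patch independently (verified to
machine precision in the tests) and is roughly 50× faster.

### Mask generation and vision pipeline

Bone and tissue labels collapse to a binary hand grid; the largest
4-connected component is kept (ties: the component whose top-left pixel
comes first in row-major order) and its interior holes are filled
(4-connected flood fill from the border). The vision pipeline then (i)
zeroes everything outside the mask, (ii) translates the masked content
so its bounding-box center sits on the image center, (iii) equalizes
the histogram over in-mask pixels only — so the zeroed background
cannot dominate the histogram; a constant region is left unchanged —
(iv) applies a 3×3 median denoise and (v) unsharp-mask sharpening
(amount 1, Gaussian sigma 1), both within the mask. The published
pipeline names these filters without parameters; the values here are
the common defaults. The stage order (equalize → denoise → sharpen)
follows the order in which the stages are described.

### Augmentation engine

Real-time augmentation enumerates four transform grids: rotation
−30…30° in 1° steps (61 values), width scale 0.85…0.99 and height scale
0.90…0.99 in 0.01 steps (150 combinations), shear x/y −5…5° in 1° steps
(121), and the photometric map `v → αv + β` with α 0.90…0.99 and
integer β 1…10 (100). Where the published prose and the published table
disagree (5° vs 1° rotation steps; 11 vs 10 α values), the table's
printed counts govern; both grids are configurable. The grand product
of the default grids is 61·150·121·100 = 110,715,000 distinct synthetic
images. `draw_augmentation()` samples uniformly from each enabled grid;
the training stream additionally applies each transform only with
probability 0.5 (the "random switch"; the probability is not stated in
the source and is configurable). Horizontal flips and translations are
never applied: bone-age radiographs are left hands by convention and
the vision pipeline already centers the content. Geometric components
are composed into a single affine transform about the image center
(rotation ∘ shear ∘ anisotropic scale) with bilinear resampling; an
identity draw is a strict no-op.

### Bone-age classifier

The classifier consumes the preprocessed 512×512 image down-sampled to
224×224 by exact area averaging and outputs a softmax over the 14
age classes; separate models are trained per sex. The desk-scale
backbone is a reduced-width inception-style network: 7×7/stride-2
convolution (8 ch), 3×3 convolution (16 ch), two inception blocks
(1×1 and 3×3 branches, 24 and 32 output channels), each convolution
batch-normalized, with max-pooling between stages and two fully
connected layers on the flattened 7×7 map. Batch normalization is the
standard conditioner for training such a stack from scratch with plain
SGD — without it, from-scratch runs at these scales frequently fail to
converge, which is also why the training harness includes the
9-combination grid search over base learning rates (0.001, 0.005, 0.01)
and gamma values (0.1, 0.5, 0.75). SGD uses momentum 0.9, weight decay
0.005 (never applied to batch-norm scale/shift), mini-batch 96 and 100
epochs by default, with the learning rate multiplied by gamma at three
evenly spaced boundaries. After the scheduled epochs the batch-norm
statistics are re-estimated exactly over the training set and a short
frozen-statistics phase fine-tunes the weights against the
inference-mode normalization at a much smaller rate — with small
mini-batches, training-mode (batch-statistics) and inference-mode
(running-statistics) predictions otherwise disagree noticeably. A
full-width topology is available behind the `backbone = "full"` flag.

Layer-wise fine-tuning is controlled by `set_finetune_depth()`: the
named group (`fc`, `inception5`, `inception4`, `conv2`, `conv1`) and
all later groups train while earlier groups freeze; `all` trains
everything from the current initialization and `scratch` re-randomizes.
When no pretrained parameters have been loaded, requesting a freezing
depth falls back to scratch behaviour with a warning — tests never
download pretrained weights. `convert_filters_grayscale()` implements
the pretrained-pathway entry point: three-channel first-layer filters
collapse to one channel by per-tap arithmetic means.

### Evaluation and attention

`evaluate_predictions()` reports top-1, within-1- and within-2-year
accuracy, RMSE in years and mAP. The source never defines its mAP;
here it is fixed as the macro average over classes present in the truth
of one-vs-rest average precision (all-points interpolation, cases
ranked by the class probability) — reported mAP values depend on this
choice. `occlusion_map()` slides a zero-filled square occluder
(default 16 px at stride 8 on the 224 input) and records the drop in
the target-class probability; `attention_on_gaps()` quantifies how much
positive attention mass falls on occluder positions overlapping the
growth-plate regions. Maturity stages use lower-inclusive half-open
bins — female [0,7), [7,13), [13,15), [15,∞); male [0,9), [9,14),
[14,17), [17,∞) — with male age 16, left unassigned by the published
ranges, folded into late puberty.

## The synthetic phantom generator

No deposited radiographs exist, so every stage is exercised on
synthetic phantoms with exact per-pixel ground truth. A phantom is a
hand-shaped arrangement of the five pixel classes rendered at nominal
intensities (bone 0.78, tissue 0.35, background 0.04, collimation 0.22,
marker 0.95 of the dynamic range), with per-phantom contrast jitter
(±10% on bone/tissue), clipped Gaussian noise (σ = 2% of the dynamic
range — mild enough to keep the classes as separable as real
bone/tissue/background are), optional collimation frame and "L" marker,
and optional whole-image inversion (white background).

The geometry is anthropometric and fixed in units of the image height,
because clinical fields are collimated to the hand — frame aspect only
changes the margins: a trapezoidal palm widest at the knuckle line
(breadth ≈ 0.45 h) narrowing toward the wrist; five splayed digits
(breadth 0.07 h, middle digit ≈ 0.29 h long) rooted into the palm's top
edge so the hand is one 4-connected component; phalanx shadows of ~70%
digit breadth (a ~2 mm soft-tissue rim); a wrist block with two bone
bars. Native heights are drawn from 512–2048 px, emulating exported
radiographs that are downscaled — never upscaled — to the working
resolution. Males get a 6% wider hand. The age signal is the
growth-plate gap: a tissue band interrupting each digit's bone bar with
width `max(0, round(12·(18 − age)/13))` px at 512-px height — linear in
age, ~12 px at 5 years, closed at 18 — whose rectangles are recorded in
the ground truth for the attention analysis.

What the phantoms deliberately do not model: carpal-bone anatomy,
texture (trabecular pattern), radiographic scatter or beam physics, and
positioning errors. Tests passing on phantoms therefore demonstrate
that the pipeline's machinery is correct and that the learning stages
can extract a localized maturity signal; they do not certify clinical
accuracy, which in the source experiments required thousands of
radiographs and full-scale pretrained networks.

## Desk-scale study conditions

The test and acceptance suites run everything at sizes a single CPU
handles in minutes; these sizes are the package's own choices:

* detector property: 1000 patches/class (the harness accepts any
  n ≥ 500), 25 epochs, evaluated as mask mIoU over 20 unseen phantoms
  at patch 32 / stride 4 — reaching ≈ 0.88 against ground truth. A
  one-hot center-label oracle pushed through the same vote aggregation
  lands at ≈ 0.85: the mean-vote plus the stride quantization bounds
  any detector at roughly that level, and the trained network
  approaches its oracle closely. The full-scale published analogue
  (1M patches, clinical images) reports 0.92.
* classifier sanity: 6 consecutive age classes (5–10) × 20 phantoms per
  class, the reduced backbone trained from scratch (base LR 0.03,
  gamma 0.5, batch 12, 160 epochs plus the frozen-statistics polish,
  15% validation holdout for the snapshot selection), then evaluated on
  freshly generated held-out phantoms. Training accuracy is read from
  the final-epoch state on the images actually trained on; held-out
  accuracy from the best-by-validation snapshot, as deployed.
* occlusion: maps on correctly classified held-out phantoms; at least
  60% of the positive attention mass must fall on occluder positions
  overlapping the growth-plate rectangles (the threshold is this
  package's own). On these phantoms the measured concentration is
  ≈0.3–0.6: a zero-filled occluder landing anywhere on a bone bar
  *creates* a dark band — the very feature that encodes a younger age —
  so the true-class probability drops over the whole skeleton, not only
  over the physes, and this check currently fails by design of the
  zero-fill convention (see limitations).

## Numerical choices and degenerate inputs

* Argmax ties in the label map break toward the earlier class of the
  fixed order; component-size ties break row-major; equalization leaves
  constant regions untouched; empty masks and missing classes raise
  classed errors (`baa_empty_segmentation`, `baa_missing_class`, …)
  rather than guessing.
* Reports with multiple conflicting bone-age statements are rejected
  (`baa_unparseable_report`): the source does not say how they were
  resolved, and a wrong guess silently corrupts labels.
* Range parsing computes the arithmetic mean in months before flooring
  to whole years, so "13 to 14 years" floors to 13; flooring is applied
  uniformly after range resolution.
* The dataset split is simple random 70/15/15 (round(0.15 N) each for
  validation and test), deterministic in the seed; a stratified variant
  exists behind a flag (off by default) for very small synthetic sets.
* All randomness flows through explicitly seeded generators; identical
  seeds give bit-identical phantoms, patch samples, training runs and
  reports (up to the report timestamp).

## Known limitations

* The phantom task is far easier than clinical bone-age reading: the
  published clinical accuracies, the fine-tuning-depth sweep results
  and the published mIoU are not reproducible here and are not claimed.
* The patch-vote aggregation intrinsically smooths mask boundaries by
  about half a patch; thin structures below ~patch-size width erode.
* From-scratch classifier training remains sensitive to the learning
  rate (high rates collapse to the class prior) — faithful to the
  source's observation that scratch runs often failed to converge; the
  grid-search harness exists for exactly this reason.
* Occlusion maps on these phantoms cannot fully isolate the physes: the
  zero-filled occluder fabricates a gap-like dark band wherever it
  covers bone, so attention spreads along the skeleton. A fill value
  matched to local tissue intensity would remove the confound, but the
  zero-fill convention matches the black-background preprocessing and
  is kept.
* The DICOM reader covers uncompressed little-endian monochrome files
  only; compressed transfer syntaxes are rejected with a format error.
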