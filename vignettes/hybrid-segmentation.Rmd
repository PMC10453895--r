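---
title: "Hybrid handcrafted-feature/CNN brain tumor segmentation: methods and design"
author: "hybridSeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid handcrafted-feature/CNN brain tumor segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the approach

Gliomas appear on multi-parametric MRI as spatially nested sub-regions with
modality-dependent contrast: peritumoral edema is bright on FLAIR and T2,
the enhancing rim is bright on post-contrast T1 (T1c), and the core is
variably hypointense on T1. BraTS-style evaluation summarizes a predicted
label map through three nested unions — whole tumor (WT, labels 1+2+3),
tumor core (TC, 2+3) and enhancing tumor (ET, 3) — each scored as a binary
segmentation.

`hybridSeg` implements a hybrid segmentation model: a U-Net-style
convolutional encoder-decoder complemented by classical handcrafted image
descriptors (dense SURF, histograms of oriented gradients, and local
intensity/texture maps) that are fused into the network along one of three
pathways. The rationale is that handcrafted channels encode explicit local
statistics and edge structure that a small CNN trained on limited data may
be slow to rediscover, while the CNN contributes learned, context-aware
features.

# Pipeline

1. **Input.** Co-registered, skull-stripped 4-modality volumes
   (T1, T1c, T2, FLAIR) with integer masks, read from NIfTI
   (`readVolume()`, `readMask()`). Registration, skull stripping and
   bias-field correction are assumed done upstream (BraTS-style input) and
   are out of scope.
2. **Normalization.** Per modality, intensities are min-max mapped to
   [0, 1] over brain voxels (`normalizeIntensity()`). The brain mask is
   taken as voxels nonzero in at least one modality; a constant modality
   maps to zero (divide-by-zero guard). This makes the map idempotent:
   after one pass the brain minimum is 0 and maximum 1, so renormalizing
   changes nothing. Robust percentile clipping is available but off by
   default — plain min-max is the simplest map onto a standard range, and
   the phantom data contain no extreme outliers.
3. **Slicing.** Axial slices are zero-padded symmetrically to the network
   input size (240 to 256 adds 8 pixels per side; `sliceDataset()`).
   Padding rather than resampling preserves label geometry exactly.
   Training drops slices with empty masks by default; inference keeps them.
4. **Handcrafted features.** `extractFeatures()` builds an image-aligned
   `FeatureStack` from one modality (FLAIR by default, where tumor contrast
   is strongest).
5. **Model.** `buildCNN()` / `buildHybrid()` construct the encoder-decoder
   with one of the fusion pathways; `trainModel()` optimizes the combined
   cross-entropy + soft-Dice objective; `finetuneModel()` re-runs at a
   tenth of the learning rate; `forwardPredict()` and `evaluateDataset()`
   produce per-region metrics.

# Handcrafted descriptors

**Dense SURF** (`dsurfDescriptors()`). Keypoints are placed on a regular
grid (`denseGrid()`, coordinates `i * step + margin`), replacing interest
point detection — on tumor MRI there is no reason to privilege blob
detections, and a dense grid gives a feature at every location. At each
keypoint, first-order Gaussian-derivative responses (scale sigma = 1.6 by
default) are collected over a square window (16 px, divisible by 4),
partitioned into 4 x 4 sub-regions; each sub-region contributes
(sum dx, sum dy, sum |dx|, sum |dy|), and the 64-vector is L2-normalized.
The 64-dimensional variant is implemented; 128 is not. Orientation
assignment (arctangent of the ratio of Gaussian-weighted response sums,
implemented quadrant-aware with `atan2`) is available but off by default:
a dense grid pipeline does not require rotation invariance, and aligned
descriptors are cheaper and more stable. Second-order (Hessian) responses
are exposed for diagnostics (`hessianResponses()`) but nothing downstream
consumes them — with a dense grid there is no detection step to threshold.
Exact Gaussian-derivative filters are used rather than box-filter
approximations: at these image sizes exactness costs nothing.

**HOG** (`hogFeatures()`). Central-difference gradients
(`imageGradients()`, replicated borders), magnitude accumulated by hard
assignment into 9 unsigned orientation bins over [0, 180) per 8-px cell,
2 x 2-cell blocks L2-normalized with an epsilon guard (1e-6). These are the
canonical defaults of the original HOG formulation, and all of them are
configurable. For fusion, each cell's raw histogram is broadcast to its
pixels, giving 9 per-pixel channels.

**Intensity/texture maps** (`textureIntensityMaps()`). Sliding-window local
mean, median and standard deviation; GLCM contrast, homogeneity and energy
from a symmetric, normalized co-occurrence matrix over 8 equal-width gray
levels (offsets (0,1) and (1,0) averaged); and an 8-neighbor LBP code map
with the neighbor >= center convention, scaled by 255 into [0, 1].
Shape-based features (area, perimeter, compactness) are deliberately
excluded as inputs: they presuppose a segmented object, so they cannot be
computed before segmentation.

**Stack assembly** (`featureStack()`). DSURF descriptors are scattered to
their grid cells and nearest-neighbor upsampled to full resolution (the
conversion of sparse descriptors to dense network channels is our design;
any image-aligned scheme would do, and nearest-neighbor keeps channels
piecewise constant and cheap). HOG and texture channels are appended
unchanged.

# The network

The encoder has four stages (channel widths 64, 128, 256, 512 at full
scale), each a 3 x 3 convolution + ReLU followed by 2 x 2 max pooling; the
decoder mirrors it with nearest-neighbor upsampling, concatenation of the
skip connection from the matching encoder stage, and a 3 x 3 convolution +
ReLU; a final 1 x 1 convolution with per-pixel softmax yields 4 class maps,
so 256 x 256 x 4 in gives 256 x 256 x 4 out. The spatial ladder is kept
strictly self-consistent — one halving per encoder stage, one doubling per
decoder stage — which is the discipline a symmetric U-Net imposes; the
channel progression (64, 128, 256, 512) and the 4-class input/output
contract are the architecture's fixed points. Skip connections are
included: they are the defining U-Net ingredient, merging low-level
localization with high-level context, and the decoder convolutions are
sized for the concatenated channels. Batch normalization is not used. Weights are He-initialized from a per-layer seed; a
hybrid model draws its non-fusion weights identically to the baseline built
from the same seed, which is what makes the zeroed-fusion equivalence test
meaningful (`zeroFusionWeights()`).

Three fusion pathways (`buildHybrid()`):

* **input_channel** — the k handcrafted channels are concatenated to the 4
  modality channels; the first convolution consumes 4 + k.
* **feature_map** — the stack is average-pooled (not nearest-neighbor,
  which would alias texture channels) to the resolution of a chosen encoder
  stage and concatenated to that stage's feature map, feeding both the skip
  connection and the deeper pathway.
* **decision_level** — the stack joins the last decoder feature map, so the
  final classifier sees width + k channels.

The engine (convolutions as one GEMM per kernel tap, explicit backward
passes, SGD with momentum) is implemented in R on base BLAS; at the
reduced sizes used here a 30-epoch training run completes in about three
minutes on one CPU core.

# Objective and metrics

The training loss is cross-entropy plus soft-Dice:
`L = CE + (1 - softDice)`, where CE is the mean over pixels of
`-log p(true class)` (probability clipped to [1e-7, 1]) and softDice is the
smoothed overlap ratio `(2 sum(y p) + eps) / (sum(y) + sum(p) + eps)`
averaged over the three foreground classes (background excluded by
default; eps = 1e-6). Care is needed with sign conventions here: "Dice
coefficient" sometimes denotes the overlap ratio and sometimes one minus
it, and mixing the two turns the objective into one that rewards *low*
overlap. This package fixes the convention so that both terms vanish at
the truth — the only arrangement under which a perfect prediction
minimizes the objective. The smoothing epsilon of 1e-6 is the conventional
choice.

Evaluation binarizes predicted and true masks per region (WT/TC/ET) and
computes accuracy, Dice, sensitivity and specificity from the pixel
confusion counts, macro-averaged over cases. Empty-denominator convention
(BraTS style): an empty ground-truth region predicted
empty scores 1.0, otherwise 0.0.

# Training recipe

SGD with momentum 0.9, learning rate 0.0010, weight decay 0.0005, batch
size 16, at most 100 epochs, early stopping on validation loss with
patience 10 (min-delta 0) and best-weights restoration — standard
practice where a recipe only says "early stopping". The validation set is
a seeded 10% of the training items. Fine-tuning after feature integration
divides the learning rate by 10 and caps epochs at 50. Dataset splitting
is a seeded shuffle with `round(fraction * n)` training cases (285 at 0.70
gives exactly 200/85). The hybrid can either be trained from scratch or
initialized from the trained baseline and fine-tuned — both paths work
(`trainModel()` accepts any model); the pipeline's default is
train-then-fine-tune on the hybrid itself.

# Augmentation

`augmentPair()` draws, per (epoch, item) seed: rotation in ±15°, scale in
[0.8, 1.2], horizontal flip with probability 0.5, elastic deformation
(displacement field of white noise Gaussian-filtered at sigma 4, rescaled
to a 10 px amplitude — published recipes rarely specify the amplitude, and 10
px is a moderate deformation at 240-256 px scale), intensity shift in
[-0.1, 0.1] with clipping to [0, 1], and per-channel histogram equalization
applied with probability 0.5. Geometry uses one backward warp about the
image center, bilinear for intensities and nearest-neighbor for labels, so
no interpolated labels can appear; exposed borders are zero. The stage
order (geometric, elastic, intensity shift, contrast) is fixed once and
documented, since more than one order is defensible. With every component
disabled the function is bit-exact identity, which the tests rely on.

# The phantom generator

`generatePhantomSlice()` emulates the *structure* of BraTS-style data, not
its anatomy: an elliptical brain on an exactly-zero background (as after
skull stripping), smooth Gaussian-filtered background texture (so GLCM/LBP
channels see nontrivial structure), and an angularly deformed disc tumor
carrying the three nested sub-regions (enhancing rim, core interior, edema
annulus) — nesting holds by construction, mirroring the WT/TC/ET
convention. Contrast offsets per modality follow the qualitative glioma
appearance (FLAIR-bright edema +0.40, T1c-bright rim +0.45, T2-bright core
+0.35, mildly hypointense T1), with additive Gaussian noise (sd 0.05)
inside the brain; these were fixed once as plausible magnitudes on
normalized intensities. Tumor radius is drawn from 1/8 to 1/4 of the image
side (capped so the edema annulus fits). Per-item seeds are derived by
hashing (seed, index), so a dataset is independent of generation order.

What passing tests on phantoms shows — and does not. The phantoms exercise
every stage end to end (I/O, normalization, features, fusion, optimization,
metrics) under controlled contrast and noise, and the training smoke test
shows the full hybrid pipeline can actually learn a nested-region
segmentation. They do not exhibit anatomical variability, multi-scanner
intensity distributions, bias fields, or ambiguous boundaries, so phantom
metric values say nothing quantitative about performance on real BraTS
volumes.

# Numerical choices and degenerate inputs

* Gaussian and derivative kernels are truncated at 3 sigma with replicated
  borders; derivative kernels are normalized to unit response on a ramp.
* Descriptors with L2 norm below 1e-12 are returned as exact zeros
  (constant-image contract).
* Softmax is computed with row-max subtraction; argmax ties break toward
  the smaller class index.
* Max-pooling routes gradients to the first maximum in fixed scan order.
* `round(fraction * n)` uses R's round-half-to-even.
* Constant modalities normalize to zero; empty keypoint grids and empty
  datasets raise informative errors rather than producing NaNs.

# Problem sizes

The test and acceptance runs use 64 x 64 phantoms (64 cases, encoder widths
8/16/32/64, HOG decision-level fusion) — small enough for a laptop core,
large enough that the learning signal is real: the 30-epoch training smoke
reliably exceeds Dice(WT) 0.8, and the full 100-epoch + fine-tune schedule
of `scripts/acceptance.R` segments all three nested regions on the held-out
split. Unit tests use 16-48 px images where brute-force
oracles (per-pixel HOG binning, pair-enumeration GLCM, loop confusion
counts, numeric gradients) remain exact and fast.

# Limitations

* 2-D per-slice modeling only; no 3-D variant is provided.
* The CNN engine is CPU-bound R; it is meant for desk-scale experiments,
  not full-resolution BraTS training.
* Handcrafted features are extracted from one modality channel at a time.
* No Hausdorff or other boundary metrics; no comparator architectures.
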