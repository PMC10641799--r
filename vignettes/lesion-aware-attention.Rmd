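---
title: "Lesion-aware attention networks for volumetric retinal OCT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-aware attention networks for volumetric retinal OCT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Diabetic nephropathy (DN) and diabetic retinopathy (DR) are both microvascular
complications of diabetes, and retinal changes visible in optical coherence
tomography (OCT) correlate with nephropathy risk. `octlan` implements a
screening classifier that separates DN from DR patients using volumetric OCT
of the macula, with an attention mechanism that concentrates the model's
capacity on lesion-prone regions instead of the whole volume. Because the
lesioned area typically occupies a small fraction of the scan, a plain
convolutional classifier spends most of its capacity on irrelevant anatomy;
the central idea here is to bootstrap a coarse lesion localization out of a
first-pass classifier and feed it back as an attention prior.

## Preprocessing

Each eye arrives as an ordered stack of 2D B-scans (400 slices of 400 x 640
pixels in the clinical geometry). The chain in `assemble_volume()` is:

1. **Macular slice selection** — keep slices with 0-based indices in
   `[130, 270)`, i.e. 140 B-scans around the macula. The half-open convention
   is deliberate: it makes the selected count exactly `slice_hi - slice_lo`.
2. **Interval sampling** — every second slice, leaving 70.
3. **Center crop** — the middle 140 columns (the foveal region), turning each
   400 x 640 slice into 140 x 640.
4. **Binarization** — Otsu's threshold on the slice histogram by default
   (`binarize_method = "fixed"` uses a constant). The threshold is applied as
   `intensity >= T`. A constant slice has no Otsu threshold and falls back to
   the fixed value.
5. **Morphological dilation** — a 5-pixel elliptical structuring element
   applied twice, to make the retinal foreground connected. Kernel size and
   iteration count are not dictated by the underlying method, so both are
   configuration fields.
6. **Foreground extraction** — connected-component labelling of the dilated
   mask, keep the largest component, fill its contour, zero everything
   outside.
7. **Resize and stack** — each masked slice is resized to 100 x 100 by
   bilinear interpolation (no aspect preservation; the masked slice is
   resized whole rather than cropped to its bounding box first), divided by
   255, and the 70 slices are stacked into a 100 x 100 x 70 volume in
   `[0, 1]`.

The module is free of randomness; running it twice yields identical bytes.
Standard image operations (Otsu, dilation, labelling, hole filling, resize)
are delegated to EBImage.

One ambiguity worth recording: "patient-based" stacking could mean merging
both eyes of a patient into one sample. We keep one volume per eye and
enforce the patient level only in cross-validation splitting, which is the
conservative reading with respect to leakage.

## The backbone

`build_backbone()` constructs a 3D residual network: a stride-2 stem
convolution (kernel 7 for the canonical depths) with max pooling, four
residual stages (basic blocks for depths 18/34, bottleneck blocks for
50/101), global average pooling, and a linear head with one score per class.
All convolutions are 3D and the depth axis is strided together with height
and width — at 70 slices the volume tolerates the four halvings, and treating
axes asymmetrically would complicate the engine for no measurable benefit at
this scale. `blocks_per_stage`, `base_channels` and the stem options allow
scaled-down variants (`tiny_backbone_config()`) for small volumes.

Two engine-level choices deserve explanation:

* **Normalization.** The canonical ResNet uses batch normalization, but the
  training regime here uses batch size 2, where batch statistics are mostly
  noise. The engine uses instance normalization (per-sample, per-channel
  statistics over space), the common choice in small-batch 3D medical
  imaging. It also makes every forward pass deterministic and independent of
  batch composition, which simplifies both Grad-CAM and the tests.
* **Implementation.** The network engine — im2col 3D convolution on BLAS
  matrix products, hand-derived backward passes, Adam — is implemented in
  vectorized base R. Every backward pass is validated against central
  differences in the test suite at 1e-6; Grad-CAM additionally carries its
  own finite-difference oracle.

Initialization is Kaiming-style (fan-out) for convolutions. No pretrained
weights exist for this input geometry, so all training is from scratch.

## Grad-CAM and the lesion mask

For a class score $y^c$ and tap-layer activations $A^k$ (channel $k$), the
channel weights are the spatially pooled gradients

$$\alpha_k^c = \frac{1}{Z} \sum_{i} \frac{\partial y^c}{\partial A_i^k},$$

with $Z$ the number of spatial positions of the tap layer, and the
localization map is $L^c = \mathrm{ReLU}(\sum_k \alpha_k^c A^k)$. The
original formulation pools over the two image axes; the model here is 3D, so
the pool runs over all three spatial axes and $Z$ is their product — the only
consistent extension. One 3D map is computed per volume (not one 2D map per
slice), again because the model itself is 3D. The default tap is the last
residual stage.

`cam_to_mask()` min-max normalizes the map to $[0, 255]$, upsamples it
trilinearly to the volume grid, and binarizes at threshold $T = 50$:
$B = 0$ if $I < T$, $1$ otherwise, so a voxel exactly at $T$ maps to 1. A
rendered-heatmap pipeline would threshold the red channel of a jet colormap
instead of the raw normalized map; the colormap adds a nonlinearity the
method does not depend on, so the raw map is the default and
`emulate_heatmap_r = TRUE` provides the rendered-channel behavior. A constant
map (no spatial discrimination at all) becomes an all-ones mask, so the
attention module degrades to plain self-attention rather than erasing the
features.

Which class drives the map is a policy choice: during training the true label
is available and is the default; at inference the predicted class is used.

## The lesion-aware attention module

At an insertion site with features $X$ (flattened to $N$ positions times $C$
channels) and the binary mask $X_B$ resampled to the site's grid (nearest
neighbor, so it stays binary):

$$X_L = X \odot X_B, \quad X_{LC} = \mathrm{conv}_{1\times1\times1}(X_L),
\quad X_C = \mathrm{conv}_{1\times1\times1}(X),$$
$$A_L = \mathrm{softmax}(X_{LC} X_{LC}^T)\, X_C + X_C.$$

The query/key features come from the mask-gated map, so attention weights are
computed from lesion-region evidence, while the values are projections of the
full features; the additive $X_C$ term keeps the original (projected)
information because the mask is only a rough localization. The convolutions
preserve the channel count, so $A_L$ replaces $X$ in the backbone.

The printed composition of this formula can also be read literally as
$\mathrm{softmax}(X_{LC} X_{LC}^T X_C) + X_C$, i.e. the softmax applied
*after* multiplying by the value matrix. That reading is dimensionally
awkward for a rowwise softmax over positions (it normalizes over channels,
not over attended positions) and does not match the self-attention mechanism
the module is modeled on, so the standard attention reading is the default;
the literal composition is implemented behind `variant = "literal"` since the
choice is the module's single biggest interpretation risk. Two further
defaults on the same grounds: no $1/\sqrt{d}$ attention scaling (the formula
has none), and the residual is `+ X_C` as printed rather than `+ X`.

Insertion is `per_stage` (after the last block of each stage, 4 modules on
the 18-layer backbone) by default; `per_block` (8 modules) reproduces the
"after each residual block" placement literally. Per-stage is the default
because attention cost is quadratic in $N = D \cdot H \cdot W$ and the
early-stage grids dominate; both are one flag apart and the tests exercise
both counts. The mask is taken as a raw binary gate rather than passed
through its own feature extractor — the simplest reading consistent with
"multiplying the features with the mask".

## Two-stage training

Stage 1 trains the plain backbone (Adam, cross-entropy, initial learning rate
$10^{-4}$, StepLR schedule, 150 epochs, batch size 2 in the clinical-scale
configuration). Stage 2 generates one Grad-CAM mask per training volume from
the stage-1 model, freezes them (mask generation is a single pass, not
refreshed per epoch), builds the attention network, warm-starts its backbone
from stage 1 with fresh attention parameters, and trains end to end.
Warm-starting is a choice — the procedure is also correct from scratch — made
because "inserting the module into the baseline model" reads most naturally
as keeping the baseline's weights, and because it converges faster at small
sample sizes; `warm_start = FALSE` gives the other behavior. The schedule
parameters (step 50, factor 0.1) and augmentation ranges (rotation ±10°,
scale 0.9–1.1) are not dictated by the method and are configuration fields.

Augmentation draws one in-plane rotation and one isotropic in-plane scale per
volume per epoch and applies the identical transform to every slice — and, in
stage 2, to the mask (nearest-neighbor, so the gated support moves with the
features). The depth axis is never resampled: slice order is anatomical.

Everything is seeded: initialization, shuffling and augmentation draw from
one stream, so a (seed, configuration) pair reproduces loss curves and final
weights bit for bit on one machine.

## Evaluation

The positive class is DN throughout. `classification_metrics()` computes
accuracy $(TP+TN)/N$, sensitivity $TP/(TP+FN)$ and specificity $TN/(TN+FP)$;
a zero denominator yields `NA` rather than an error, and such folds are
excluded from cross-validated means with a warning. `make_folds()` splits at
the *patient* level (all eyes of a patient share a fold) to prevent leakage;
`crossvalidate()` averages per-eye DN probabilities to one probability per
patient before thresholding at 0.5, on the view that screening produces one
decision per patient. ROC curves sweep all unique scores and AUC is
trapezoidal (cross-checked against pROC in the tests).

## The phantom generator

Clinical OCT cohorts are not distributable, so `phantom_spec()` /
`generate_dataset()` produce synthetic B-scan stacks with the geometry the
pipeline assumes: a dark background, a few smooth bright curved bands
(polynomial center curves with a slow sinusoidal drift across slices) for the
retinal layers, additive Gaussian noise, and — for DN-labeled eyes — a
hyperreflective spherical lesion placed inside the central ~35% of slices and
columns, so the macular crop retains it. All geometry derives
deterministically from the spec's seed; identical specs give bit-identical
stacks. `study_phantom_volumes()` fixes the desk-scale study conditions used
by the package's own experiments: 96 x 96 x 64 stacks, 3 bands, lesion radius
10 px, noise sigma 5, preprocessed to 48 x 48 x 16.

What the phantom does *not* emulate: OCT speckle statistics, vascular or
OCTA structure, pathology other than a bright blob, acquisition artifacts.
Passing the package's experiments on phantoms therefore demonstrates that the
pipeline is implemented correctly and that the attention mechanism can
exploit a localized class signal — it says nothing about clinical accuracy,
which can only be assessed on real cohorts.

## Problem sizes and numerical choices

The package's experiments and tests run at deliberately small scale, chosen
so a full run stays in minutes on one CPU core: 20-patient phantom studies,
48 x 48 x 16 volumes, a two-stage tiny backbone (8 base channels), 20–25
epochs at learning rate $10^{-3}$ (the higher rate suits the small parameter
count; the clinical-scale default remains $10^{-4}$), and 3 seeds for the
baseline-vs-attention comparison, reported as the median. At this sample size
(8 training volumes per cross-validation fold) held-out performance under
noisy phantoms varies with the dataset draw even when training accuracy
saturates, so the cross-validation demonstrations use the noise-free
separable dataset, where held-out accuracy saturates for most seeds and the
fixed-seed test reaches exactly 1.0. Gradient checks use
central differences with step $10^{-5}$ against analytic gradients at
tolerance $10^{-6}$; the Grad-CAM oracle tolerance is $10^{-3}$ with step
$10^{-4}$. Degenerate inputs have defined behavior throughout: empty
foreground masks return the slice unchanged (with a warning), constant
localization maps give all-ones attention masks, single-class training sets
and undersized stacks raise errors naming the requirement, pooling ties break
to the first position.

## Known limitations

* The engine is CPU-bound base R; clinical-scale training (100 x 100 x 70,
  depth 18+, 150 epochs) is out of reach at desk scale. The architecture code
  is nonetheless the full family (18/34/50/101), exercised at reduced width.
* Attention memory is quadratic in the number of spatial positions at the
  insertion site; `per_block` insertion at early stages of large volumes is
  expensive by construction.
* The phantom's class signal is a single bright blob; it cannot measure
  robustness to subtler lesion morphologies.
* Checkpoints are R serialization files, not interoperable with other
  frameworks.
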