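---
title: "Shape-prior-constrained V-Net segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-prior-constrained V-Net segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stvnet)
```

## The problem and the model

Segmenting the proximal femur from quantitative CT is the gateway to
finite-element bone-strength analysis, which needs an accurate femoral
surface. A plain voxelwise segmentation network optimizes overlap but
not surface plausibility: predictions tend to under-segment and to carry
rough surfaces, particularly where thick slices under-sample the
femoral head.

`stvnet` couples two sub-networks:

* a **3D V-Net segmenter**: an encoder of `levels` blocks (3x3x3
  convolutions, batch normalization, ReLU) with 2x max-pool
  downsampling, mirrored by a transpose-convolution decoder with skip
  connections that concatenate each pre-pool encoder feature map onto
  the matching decoder map; dropout precedes a final 1x1x1 convolution
  and logistic output, giving a per-voxel foreground probability `Y'`;

* a **spatial transformation module**: given the two-channel stack of
  `Y'` and a shape prior `S`, four conv/pool stages and a fully
  connected head regress the 12 entries of a 3x4 affine `phi` mapping
  target voxel coordinates to source coordinates. The deformed
  prediction `Y''` is produced by trilinear (hat-kernel) resampling of
  `Y'` on the grid `phi %*% c(x, y, z, 1)`.

The shape prior is not hand-drawn: it is the Otsu-binarized network
prediction, enlarged and smoothed by morphological dilation with a
5x5x5 structuring element. The transformation branch therefore acts as
a learned regularizer: the compound objective

```
L = alpha * L_dice(Y', Y) + beta * L_dice(Y'', Y) + gamma * L2
```

(defaults `alpha = 1`, `beta = 0.1`, `gamma = 0.2`) rewards predictions
whose dilated-and-realigned silhouette also matches the ground truth.

## Differentiability of the resampler

The sampler is the load-bearing piece: the module can only be trained
end-to-end if gradients flow through the interpolation with respect to
both the source voxels and the sampling coordinates. The hat-kernel
weight `max(0, 1 - |x - m|)` has derivative `+1` for `m - 1 < x <= m`,
`-1` for `m < x < m + 1`, and `0` outside; the implementation takes the
`x <= m` branch at exact integer coordinates (ties to `+1`). Both
partials are implemented analytically in C++ and are verified against
central finite differences and against a literal triple-sum oracle in
the test suite. Coordinates are raw 0-based voxel indices — not
normalized — so the printed interpolation formula is testable verbatim;
out-of-grid coordinates contribute zero (no clamping).

Two genuine non-smooth points exist and are excluded from
finite-difference checks by construction, not by tolerance-widening:
the exact identity transform places every sampling coordinate on a
kernel node, and a freshly initialized network sits exactly on the ReLU
kink wherever batch normalization collapses a 1-voxel feature map to
its `beta` offset.

## Three-stage training

* **Stage I** trains the V-Net alone (`alpha`, `gamma` terms); any
  transformation-module weights are bitwise frozen.
* **Stage II** freezes the V-Net, generates one prior per training
  sample from its outputs at stage entry, and trains the
  transformation module under the `beta` term; the priors stay fixed
  within the stage.
* **Stage III** trains everything jointly under the full objective.
  After each epoch, if the validation DSC exceeds the best seen, all
  priors are regenerated from the current V-Net output, so the stored
  best DSC is monotone nondecreasing.

Each stage logs per-epoch training loss and validation DSC (hard,
Otsu-binarized Dice averaged over validation subjects — computed on a
held-aside validation fold rather than on training data, to avoid the
update rule reinforcing its own targets) and retains the
highest-validation-DSC weights. The Adam state is re-initialized at
each stage boundary, the usual choice for staged fine-tuning.

The Dice losses in the printed objective contain the non-differentiable
binarization `G`; training uses the standard probability-sum relaxation
(smoothing term `1e-6` in numerator and denominator) and all reported
metrics use hard `G`. The L2 term excludes biases and batch-norm
parameters. `l2_penalty()` reports the raw sum of squared kernel
entries; the optimized objective uses the per-weight average
(`l2_penalty(model, average = TRUE)`), because a raw sum over millions
of weights at `gamma = 0.2` would exceed the bounded Dice terms by
orders of magnitude and weight decay would dominate the optimization —
no network of this size could converge under that reading of the
objective.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha, beta, gamma` | 1, 0.1, 0.2 | loss mix: segmentation overlap, aligned-prior overlap, L2 |
| `dropout_keep` | 0.8 | keep-probability before the output convolution |
| `base_width` | 40 | channels of the first encoder block, doubled per level; 40 puts the full profile near 8.6 M weights, the tiny profile uses 4 |
| `lr` | 1e-4 | Adam learning rate (full-scale setting) |
| window `depth`, `step` | 32, 1 | depth-wise sliding-window inference; overlapping windows fused by the arithmetic mean |
| prior element | 5x5x5 cube | dilation structuring element |
| crop | 192x192 | in-plane region of interest fed to the network |

The phrase defining the structuring element ("unit diagonal matrix" of
size 5x5x5) is geometrically a diagonal line of five voxels, which
cannot enlarge a mask isotropically or smooth its surface — the stated
purpose of the dilation. The default is therefore the all-ones 5x5x5
cube; the literal diagonal remains available
(`structuring_element("diag5")`, config key `prior.element: diag5`).
Similarly, "dropout probability 0.8" is read as a keep-probability of
0.8, the convention of the framework family the model class comes
from.

## Slice-thickness conversion

Acquisitions with 2 mm slices are converted to 3 mm by Fourier
interpolation over non-overlapping groups of three contiguous slices —
each group is spectrally zero-padded (centred spectrum, Nyquist-bin
splitting for even lengths, scaling that preserves constants) from
three to six 1 mm slices, then decimated by averaging consecutive
triples into two 3 mm slices. Constants are fixed points and the group
mean (DC component) is preserved to numerical precision; slice counts
that are not a multiple of the group size are rejected rather than
padded, since the procedure is defined on complete groups.

## The phantom generator

The clinical cohort behind the method (~400 QCT subjects) is not
deposited, so the package ships a synthetic femur-like phantom
generator that stands in for it: a spherical head joined by an oblique
cylindrical neck (configurable neck angle) to a vertical shaft, a
brighter cortical shell of configurable thickness, soft-tissue
background, additive Gaussian noise, and anisotropic spacing (0.9 x
0.9 x 3 mm by default) so the millimetre scaling of the surface
metrics is genuinely exercised. Cohorts are stratified: "male-like"
subjects get contrast 0.9-1.0 and "female-like" subjects 0.5-0.65,
emulating the direction of the reported sex difference in bone density
and hence image contrast; geometry is jittered ±10% per subject, and
slice counts can be drawn from 37-95 to exercise sliding-window
inference.

What the phantoms do **not** emulate: beam hardening, trabecular
texture, neighbouring bones (pelvis, contralateral femur), metal
artefacts, or inter-subject anatomical variation beyond similarity
transforms of three primitives. Tests passing on phantoms therefore
establish that the pipeline's machinery is correct and that the
shape-prior mechanism helps on bright-foreground anisotropic volumes —
not that clinical-grade accuracy transfers to real QCT.

## Numerical and design choices

* **Axis convention**: arrays are indexed (row, column, slice), 0-based
  voxel coordinates throughout; only names suffixed `_mm` are physical.
* **Otsu binarization** uses 256 bins on [0, 1]; the reported threshold
  is the lower edge of the first foreground bin and voxels at or above
  it are foreground. Constant maps yield an all-background mask with a
  warning.
* **Surface metrics**: surfaces are 6-connectivity boundary voxels
  (outside the grid counts as background); HD and ASD are directed
  (prediction to truth), as the metric definitions state, with
  symmetric variants also reported. Distances are in mm. Reported ASD
  is true millimetres; no normalization is applied.
* **Empty-vs-empty Dice** is 1 (two empty masks agree); an empty mask
  on one side only is an error for surface metrics and a warned `NaN`
  for sensitivity/specificity.
* **Sliding-window fusion** is the arithmetic mean of overlapping
  window predictions (max fusion behind a flag); fusion precedes
  binarization, which is described as the final step.
* **Regressor initialization**: the fully connected head starts at zero
  weights with the identity transform as bias, so training begins from
  the untransformed prediction — the stability-critical convention for
  spatial transformers.
* **Regressor output scaling**: the fully connected weight path is
  scaled by `min(1, 32 / n_flat)`, where `n_flat` is the flattened
  feature length. Without it, adaptive per-coordinate optimizer steps
  on a wide flat layer move the affine by large amounts per update,
  the resampled volume leaves the grid entirely, and training stalls
  on the resulting zero-gradient plateau. The scaling makes the
  transform's per-step motion independent of the grid size and leaves
  the identity initialization untouched.
* **No determinant constraint** is imposed on `phi`; nothing in the
  model definition requires one.
* **Rotation augmentation** operates in voxel-index space (angles
  uniform within ±15° per axis, trilinear for the volume,
  nearest-neighbour for the mask). With anisotropic spacing this is a
  shear in physical space; for augmentation purposes plausible
  variation matters more than geometric exactness.
* **Batch size** is one volume (memory-safe default; the batch
  dimension is not load-bearing anywhere).

## Scaled-down experiment profile

The desk-scale analogue of the full study trains tiny profiles
(64x64x32 grids, `base_width` 4, one convolution per block, regressor
widths 8/16/32/64) on 40 stratified phantoms with stage schedule 6/3/6
and learning rate 1e-3 (`training_config_desk()`). The small network
tolerates the larger rate and converges within a few epochs on the
phantom task; 10% of subjects are held out, fold 1 of the remainder is
the internal validation set, and the same split serves the stage-I
V-Net baseline and the full three-stage model, so their held-out
comparison is paired. The affine-recovery experiment trains the
transformation module alone on pairs (known-affine-deformed mask,
original mask) at 32x32x16 and checks held-out aligned Dice. Both run
in minutes on one CPU; all quantitative statements about them are
computed by the test suite and the acceptance script at run time, not
quoted.

## Known limitations

* The transform is affine only; it cannot express local deformation of
  the prior (a deformable extension would change the module contract).
* The CNN layers are implemented in this package (C++ kernels with
  hand-derived backward passes) rather than on a GPU framework;
  full-scale 192x192x32 training with `base_width` 40 is possible but
  slow on a CPU — the package's experiments use the tiny profiles.
* NIfTI is the supported volume format (read and write); NRRD and
  DICOM-series inputs are out of scope for this implementation.
* `update_priors()` acts at epoch granularity; batch-granular updates
  are not implemented.
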