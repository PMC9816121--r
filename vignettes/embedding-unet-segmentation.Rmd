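---
title: "Automated HR-pQCT segmentation with an embedding-predicting U-Net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated HR-pQCT segmentation with an embedding-predicting U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-resolution peripheral quantitative computed tomography (HR-pQCT) images
the distal radius and tibia in vivo at an isotropic voxel size of 60.7 µm.
Quantitative morphometry of bone microarchitecture requires a semantic
segmentation of each scan into three regions: the *cortical* compartment
(dense shell), the *trabecular* compartment (interior lattice of struts and
marrow) and the background. Two surfaces separate them — the *periosteal*
surface between background and cortex, and the *endosteal* surface between
cortex and trabecular bone. The semi-automated gold-standard protocol needs
manual inspection and correction, which is slow and injects inter-operator
bias. `pqctseg` implements a fully automated alternative: a multi-slice 2D
U-Net that predicts level-set embeddings of the two surfaces, followed by a
deterministic morphological post-processing procedure that enforces the
anatomy's topology.

## The model

### Embedding fields instead of class labels

The network does not emit class probabilities. For each axial slice it
produces two scalar fields, $\phi_{\mathrm{endo}}$ and
$\phi_{\mathrm{peri}}$, whose zero level sets are the endosteal and
periosteal surfaces: the sign says inside/outside, the magnitude
approximates the distance to the surface in voxels. Masks follow from signs
alone,

$$\text{trabecular} = \{\phi_{\mathrm{endo}} < 0\}, \qquad
  \text{cortical} = \{\phi_{\mathrm{endo}} > 0 \wedge \phi_{\mathrm{peri}} < 0\},$$

with zero-valued voxels assigned to neither mask (strict inequalities make
the masks disjoint by construction; the zero set has measure zero in
practice). Predicting surfaces as embeddings lets the losses reason about
surface geometry — curvature, distance-function validity — which a plain
softmax segmentation cannot express.

### Architecture

The backbone (`unet_config()`, `build_unet()`) is the classical 2D U-Net
encoder–decoder with skip connections, with three modifications: 'same'
padding in all 3×3 convolutions (output resolution equals input
resolution), group normalization plus dropout inside every double-conv
block, and five adjacent axial slices stacked on the channel axis as input
while only the center slice is predicted. Missing neighbors at the first
and last slices are mirror-reflected without repeating the edge slice
(indices 3, 2, 1, 2, 3 for the first slice). A 3D prediction is assembled
by sweeping the model over the axial axis (`predict_volume()`); each
slice's prediction is independent of the others.

The exact channel widths per level are configuration, not substance: the
defaults (`base_channels = 32`, `depth = 4`) give a capacity in the spirit
of the original design, and all tests and acceptance checks are written so
that they do not depend on exact capacity. The nonlinearity is ReLU and
upsampling uses 2×2 stride-2 transposed convolutions, both matching the
original U-Net; neither choice is load-bearing. Because no deep-learning
framework is available in R, the forward and backward passes are authored
here directly — convolution gather/scatter in C++, all heavy linear algebra
through BLAS — and the backward pass is verified against finite differences
in the test suite.

## Losses

Embedding fields are converted to class probabilities with a smoothed
Heaviside $H_\epsilon(x) = \tfrac12 + \tfrac1\pi \arctan(x/\epsilon)$:

$$p_{\mathrm{trab}} = H_\epsilon(-\phi_{\mathrm{endo}}), \quad
  p_{\mathrm{cort}} = H_\epsilon(\phi_{\mathrm{endo}})\,
                      H_\epsilon(-\phi_{\mathrm{peri}}), \quad
  p_{\mathrm{back}} = H_\epsilon(\phi_{\mathrm{peri}}),$$

normalized per voxel to sum to one, and scored against the one-hot
reference masks with the mean cross-entropy $L_{CE}$ (natural log,
probabilities floored at $10^{-12}$). Two regularizers act on each field:

* **Curvature penalty** $L_\kappa$: the level-set curvature is the
  divergence of the unit normals,
  $\kappa = \nabla\!\cdot(\nabla\phi / |\nabla\phi|)$, computed with
  central differences (one-sided at borders) and an $\eta = 10^{-8}$
  stabilizer in the denominator. On the zero-crossing band $\delta(\phi)$
  (voxels equal to zero or with a 4-neighbor sign change) the loss is the
  mean of $\delta(\phi)\,\mathrm{ReLU}\!\big((\kappa/\kappa_{\mathrm{thresh}})^2 -
  1\big)$. The threshold is physical: $\kappa_{\mathrm{thresh}} =
  0.005\,\mu m^{-1}$, i.e. $0.3035$ voxel$^{-1}$ at 60.7 µm voxels, so only
  surface wiggles tighter than a ~200 µm radius of curvature are penalized.
* **Signed-distance penalty** $L_{|\nabla\phi|}$: a true signed distance
  function has $|\nabla\phi| = 1$ off the surface, so the loss is the mean
  of $(1 - \delta(\phi))\,\log^2 |\nabla\phi|$ (magnitude floored at
  $10^{-8}$). It discourages degenerate embeddings and makes the discrete
  curvature estimate meaningful.

The total is
$L = L_{CE} + \lambda_\kappa (L_{\kappa,\mathrm{endo}} +
L_{\kappa,\mathrm{peri}}) + \lambda_{|\nabla\phi|}
(L_{|\nabla\phi|,\mathrm{endo}} + L_{|\nabla\phi|,\mathrm{peri}})$ with
both $\lambda = 10^{-4}$, so classification dominates early training and
the regularizers reach the same order of magnitude near convergence.

Numerical choices that the formulas leave open, and how this package fixes
them: $\epsilon = 1$ voxel (the transition width of the Heaviside matches
the one-voxel localization of a surface on the grid); every loss term is
reduced by the mean over all slice voxels, which keeps the $\lambda$s
independent of image size; the band uses 4-connectivity (8-connectivity is
available and widens the band by at most one voxel); and the analytic loss
gradient treats $\delta(\phi)$ as locally constant — it is piecewise
constant in $\phi$, so this is the exact subgradient almost everywhere.
All gradients are validated against finite differences.

## Pre-processing

Scanner-native values are calibrated to densities (mg HA/cm³) by an affine
map whose constants are scanner-specific and must be supplied by the user
(`calibrate_native_to_density()`). Densities are truncated to
$[-400, 1400]$ mg HA/cm³ and mapped linearly to $[-1, 1]$ via
$\bar\rho = (2\rho' - 1000)/1800$; the anchors $-400 \to -1$,
$1400 \to 1$, $275 \to -0.25$ are exact, and $-0.25$ reappears later as the
bone-mask density threshold. The coronal and sagittal extents are padded to
one common multiple of eight — read as a single shared value because square
slices simplify the network and "the same multiple" is singular — with the
truncation floor $-400$ (i.e. $-1$ after standardization) so padding looks
like background; masks pad with zeros, and odd pad widths put the extra
voxel on the high side.

## Training protocol

`fit_unet()` reproduces the published protocol: AdamW (decoupled weight
decay 0.01, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$ — the optimizer's
canonical defaults) under a one-cycle schedule with linear ramps: the
learning rate rises $10^{-4} \to 10^{-3}$ over a 10-epoch half-cycle,
falls back over the second half-cycle, and then anneals over 5 convergence
epochs; momentum ($\beta_1$) mirrors the cycle inversely between 0.95 and
0.85. The cited one-cycle policy does not fix the final annealed rate; this
implementation anneals to `lr_min / 25`, the convention of the policy's
reference implementations, exposed as `final_lr_fraction`. Each epoch
shuffles the images, then shuffles the axial slices within each image and
consumes them in batches of 4 drawn from a single image (a 168-slice scan
yields exactly 42 batches). Trailing partial batches are kept — the
published image size divides evenly, so the question never arose there.
One evaluation-mode pass over the validation set closes every epoch.
Training is fully seeded and repeatable on a single device; multi-device
nondeterminism is out of scope.

## Morphological post-processing

Raw sign-thresholded masks can contain speckle, holes, and pieces of the
secondary bone (ulna/fibula). Three filters repair them
(`postprocess_segmentation()`):

1. **Iterative binary segmentation filter** — an alternating sequential
   filter with Euclidean-ball structuring elements of radius
   $r = 1, 2, \dots$ and two connectivity steps spliced in: inside each
   open (erode → dilate), only the largest 26-connected foreground
   component survives between the two steps; inside each close
   (dilate → erode), only the largest 6-connected background component
   survives, i.e. every enclosed cavity is filled. Maximum radii are 5/15
   voxels (open/close) for network masks and 3/15 for the density mask.
   Erosion and dilation are computed exactly via the squared Euclidean
   distance transform, which reproduces integer-radius ball structuring
   elements voxel-exactly.
2. **Minimum cortical shell filter** — the filtered trabecular mask dilated
   by 8 voxels (≈ 0.5 mm) minus the mask itself: a shell that guarantees a
   minimum cortical thickness around the trabecular compartment.
3. **Morphological bone mask filter** — the first step of the classical
   dual-threshold algorithm: binarize the standardized image at $-0.25$
   (275 mg HA/cm³), apply a 3×3×1 in-plane binary median filter, then the
   iterative filter. This density-only bone mask is a safety net against
   the network missing part of the bone.

The full procedure: filter the raw trabecular mask (1); derive the shell
(2); filter the raw whole-bone mask (cortical ∪ trabecular) (1); compute
the density bone mask (3); union all four into the final bone mask; and
subtract the filtered trabecular mask to obtain the cortical mask. The
published description fixes the filters and the guarantees (single
component per compartment, no background gaps between compartments, a
minimum-thickness shell, subtraction of trabecular from bone, unions where
paths converge) but the exact dataflow is reconstructed here; it is
isolated in one function so alternate wirings can be swapped in.

**Border conventions.** Discrete morphology near the grid border is
underdetermined, and the common default (treat off-grid as background in
every erosion) annihilates any volume thinner axially than about twice the
open radius — irrelevant for 168-slice scans, fatal for desk-scale
volumes. This package therefore (a) computes the open's erosion relative
to the *observed* background, so a bone spanning the axial scan ends is
not trimmed there, and (b) runs each close on a grid padded by its radius,
which keeps the close extensive near borders and guarantees that the
outside background is a single — and the largest — component when the
largest-background-component rule is applied. On large clinical grids
these conventions coincide with the common defaults everywhere away from
the border.

## Evaluation, agreement and precision

`overlap_metrics()` reports Dice and Jaccard (defined as 1 when both masks
are empty). `surface_distances()` extracts boundary voxels by 6-connected
erosion difference and uses exact distance transforms; ASSD is the mean of
the pooled surface distances in both directions and the Hausdorff distance
their maximum, both in mm. `bland_altman()` and `linear_agreement()`
implement the mean-error ± 1.96 SD limits of agreement and OLS with
± 1.96 SE confidence intervals. For repeat-scan precision,
`precision_stats()` uses the two-replicate formulas
$SD_i = |x_1 - x_2| / \sqrt 2$, $\%CV_i = 100\,SD_i/\bar x_i$ (pair mean in
the denominator, the standard densitometry convention), RMS over
participants, and $LSC = 2.77 \times RMS\,SD$ — the 95%-confidence
least-significant-change multiplier for two measurements per timepoint;
the multiplier is exposed. `compare_precision()` mirrors the published
analysis: D'Agostino–Pearson $K^2$ normality on the individual SDs and a
two-sided Wilcoxon signed-rank test with Pratt zero handling on the paired
SDs; both tests are implemented in the package (verified against reference
implementations) because no installed R package provides them.

## The phantom generator

Real HR-pQCT data with reference segmentations is not publicly available,
so `generate_phantom()` provides the package's test and demonstration
data: per slice, a high-density cortical annulus (900 mg HA/cm³ by
default) around a trabecular interior whose density is a thresholded
band-limited texture (struts at 350, marrow at 50, mean 200), a slow axial
drift of the bone center, optional low-density cortical pores, an optional
smaller secondary bone near the image edge, and additive Gaussian noise
(SD 30 mg HA/cm³) clipped to the calibration range. The default densities
put the $-0.25$ threshold (275 mg HA/cm³) between cortex and trabecular
mean, exercising the bone-mask filter's cavity-filling path. Because the
surfaces are analytic circles, the ground-truth masks *and* the
ground-truth signed-distance embeddings are exact, which is what makes the
loss-function oracles possible ($|\nabla\phi| = 1$ off-surface; band
curvature $= 1/R$). `generate_repeat_pair()` rigidly displaces the same
anatomy with fresh noise to emulate same-day repeat scans with
repositioning, returning the true transform. `stratified_split()`
reproduces the cohort-splitting procedure: participants stratified by
study, binned into quartiles of their minimum total BMD across images, and
assigned 70/15/15 within bins with a largest-remainder rule on cumulative
quotas (overall sizes match the fractions to within one participant); all
images of a participant stay together.

What the phantom deliberately does **not** emulate: real plate-and-rod
trabecular microarchitecture, partial-volume blur at surfaces, beam
hardening, rings, or motion artifacts, and its repeat-scan texture is not
rigidly transported with the anatomy (only the geometry and noise are).
Passing the phantom-based tests therefore demonstrates that the training
machinery, losses, post-processing and metrics behave as specified on
images with the right large-scale structure and contrast — not that the
shipped configuration reaches clinical-grade accuracy on scanner data;
that requires training on real scans with expert reference masks.

## Desk-scale problem sizes

The shipped tests and the acceptance script exercise the full pipeline at
sizes chosen for a single CPU: phantoms of 64×64 in-plane voxels and 6
slices (outer radius 1.5 mm, cortical thickness 0.6 mm), a reduced-capacity
network (depth 2, 12 base channels, group size 4), and a compressed
one-cycle schedule (5-epoch half-cycle, 2 convergence epochs, learning
rates scaled up one notch to 2×10⁻⁴…2×10⁻³ for the short run). Under
these conditions a model trained on 8 phantoms segments held-out phantoms
with post-processed Dice above 0.95 per compartment, one connected
component each, and the trabecular compartment separated from background
by at least the 8-voxel shell. The full-size configuration (168 slices,
depth 4, 32 channels, 10/5 epochs) is the default of the exported
functions.

## Known limitations

* The embedding U-Net trains on CPU via BLAS; it is deterministic and
  exact but not fast. Training clinical-scale models is feasible in
  principle and slow in practice.
* The curvature penalty's discrete estimate is only accurate for radii
  ≳ 10 voxels; at the default threshold (≈ 3.3 voxels) the penalty acts as
  a soft detector of sub-voxel-scale wiggles rather than a precise
  curvature measurement — same as any central-difference implementation.
* Rigid registration of repeat scans is accepted as an input (the phantom
  pair returns its true transform); no registration algorithm is included.
* Manufacturer morphometric outputs (Ct.Po, Tb.N, …) and the AIM file
  format are out of scope; `compartment_summaries()` provides only simple
  density/area descriptives, and sub-group analyses are driven by
  user-supplied parameter tables via `quartile_subgroup()`.
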