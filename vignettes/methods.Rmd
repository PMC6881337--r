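---
title: "Physics-informed deep non-contrast synthesis from dual-energy CT: methods"
author: "dectdnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-informed deep non-contrast synthesis from dual-energy CT: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dual-energy CT (DECT) acquires a low-kVp and a high-kVp image of the same
anatomy. Physics-based three-material decomposition can "subtract" iodinated
contrast from the pair to form a virtual non-contrast (VNC) image, but the
decomposition splits the dose between the derived images and ignores
anatomic context, so VNC images are noisier and systematically offset from
a true non-contrast (TNC) acquisition. `dectdnc` implements a two-stage
post-processing framework:

1. **Physics stage.** A 2-D *lookup image* over (low HU, high HU) bins is
   estimated from training pairs and their vendor-style VNC values,
   unobserved cells are imputed with a DCT-based penalized-least-squares
   inpainter, and the table is applied (plus 5x5 median filtering) to give
   a lookup VNC, **L-VNC**.
2. **Learning stage.** A residual convolutional network with dilated
   convolutions is trained on (low, high, L-VNC) inputs to predict the
   *difference* TNC - L-VNC inside the brain mask. Adding the predicted
   difference to L-VNC composes the deep non-contrast image, **DNC**.

All quality metrics — RMSE and Spearman rank correlation over batches of
pooled brain voxels — compare DNC, L-VNC and the decomposition VNC against
TNC.

## The synthetic phantom and what it emulates

Clinical DECT cohorts are not redistributable, so the package ships a
generator whose defaults define the study conditions used by the test
suite and the acceptance script:

* **Scenes.** An elliptical "brain" (28-55% of a 64x64 raster) subdivided
  into CSF (ventricles + sulcal rim), gray and white matter with smooth
  random boundaries, and optional elliptical hemorrhage lesions. Mean HU
  per class: background -1000, CSF 8, white 25, gray 38, hemorrhage 65.
* **Iodine.** A smooth non-negative concentration map (Gaussian foci plus
  a mild uniform perfusion level) confined to the brain. The forward model
  is linear: one concentration unit adds `g = 25` HU at the high energy
  and `r * g = 53` HU at the low energy, with the protocol iodine ratio
  `r = 2.12`. Beam hardening and projection-domain effects are out of
  scope.
* **Spectral structure.** Two named physics presets, "80/150Sn" and
  "100/150Sn", differ in noise (sigma_low 3.5 vs 2.5 HU; sigma_high 2.0)
  and in small per-class spectral tilts (<= 3 HU), so the (low, high)
  distribution is not trivially rank-1.
* **TNC spectral offset.** The TNC series is a single-energy acquisition
  whose effective spectrum matches neither DECT energy, so each tissue
  shows a systematic TNC-vs-VNC offset. The default per-class offsets
  (CSF -3, white +6, gray +9, hemorrhage +14 HU) emulate that
  anatomy-dependent discrepancy; it is exactly the signal the residual
  network learns, and the scale of these offsets (up to ~15 HU) sets the
  size of the improvement the DNC can demonstrate over L-VNC.
* **Partitioning.** Scenes play the role of patients; each is assigned to
  exactly one of train/validation/test (default fractions
  0.745/0.145/0.110) by largest-remainder apportionment with a guaranteed
  minimum of one scene per partition.

Gaussian per-pixel noise (independent per energy) stands in for CT noise;
correlated noise textures, 3-D anatomy, registration error and skull
stripping are *not* emulated — passing tests demonstrate the pipeline's
internal consistency and the direction of the learning benefit, not
clinical-scale error magnitudes.

## The material-decomposition stand-in

The vendor decomposition is proprietary, so the package uses the textbook
image-domain three-material model: each (low, high) pixel p is written

    p = w + a (b - w) + c d,

with `w` the water point (0, 0), `b` the hemorrhage point, and
`d = (r, 1)` the iodine direction. The iodine image is `c`; the scalar VNC
blends the iodine-free point with weight `mu = 0.5` on the low-energy
coordinate. The default hemorrhage point (68, 62) gives the base materials
a small spectral separation and maps the hemorrhage material to VNC 65.

One consequence deserves emphasis. Under the simulator's forward model a
spectrally flat tissue sits at (b, b) on the identity line, and the
vendor-style basis maps that point to `1.1476 b`, not `b` — a
proportional, anatomy-dependent VNC bias, which is precisely the kind of
systematic error real decompositions show and the network corrects. When
the *physics consistency* of the chain itself is being verified (the
"loop closure" tests: noiseless, zero-tilt simulation, then
decomposition, must reproduce the rendered TNC to 1e-6 HU), the tests use
`neutralBasis()`, whose hemorrhage point (65, 65) lies on the identity
line at the same VNC value; with it the decomposition is exact on
spectrally flat tissue while still removing iodine exactly. Both bases
expose the same iodine direction, and iodine invariance holds for any
basis.

## The lookup table

* **Bins.** 1-HU square bins over [-200, 400] HU per axis (600 cells per
  axis). The range covers skull-stripped brain plus contrast enhancement;
  out-of-range samples are clamped to edge bins and counted.
* **Aggregation.** A cell's value is the arithmetic mean of the VNC values
  of the training pixels that fell into it — the minimizer of the squared
  error the downstream metrics use.
* **Inpainting.** Unobserved cells are imputed by the iterative DCT
  penalized-least-squares smoother: 100 iterations with the smoothing
  parameter decreasing geometrically from 1e3 to 1e-3, re-imposing
  observed cells after each step. The cosine basis has a zero-slope
  (Neumann) boundary condition that biases extrapolation of tilted
  surfaces near the table edge, so the least-squares plane through the
  observed cells is removed before smoothing and restored afterwards; the
  VNC surface is close to planar, so the smoother only imputes curvature.
  A fully empty table is filled with zeros. With these choices a 60x60
  linear surface with half its cells deleted is recovered to machine
  precision inside the observed convex hull.
* **Application.** Nearest-cell lookup with edge clamping. In-sample, the
  L-VNC reproduces the reference VNC to within the bin quantum (masked
  RMSE <= 0.5 HU on noiseless scenes).
* **Filtering.** The raw L-VNC is median filtered (5x5, symmetric-reflect
  borders) before it is used as a network input channel and before the
  residual target is formed.

## The residual network

Architecture (spatial resolution preserved throughout):

* a 3x3 projection lifting the 3 input channels to `channels`;
* 3 groups of 3 residual blocks with dilations 1, 2, 4 (both convolutions
  of a block use the group's dilation); block = conv -> batch norm -> ReLU
  -> dropout -> conv -> batch norm, added to the block input;
* a final 1x1 convolution to one channel.

Inputs are the low, high and median-filtered L-VNC channels, each affinely
mapped from the HU window [-100, 300] to [0, 1]; the target difference
stays in raw HU, so the network output is read directly as HU. The loss is
the RMSE over the pooled brain-mask voxels of each batch plus an L2
penalty (0.02) on convolution weights; optimization is Adam at a constant
learning rate. "Trained until the validation loss plateaus" is
operationalized as early stopping: no improvement > 0.01 HU for `patience`
epochs, returning the best-validation weights. Everything (initialization,
data order, dropout) derives from one seed; two runs with the same seed
agree to at least 1e-6 relative.

Two profiles are provided. The *clinical* profile (64 channels, 256x256
inputs, batch 8, learning rate 1e-5, dropout 0.5) mirrors the
clinical-scale configuration. The *desk* profile used by the synthetic
study (8 channels, 64x64 inputs) raises the learning rate to 1e-3 and
lowers dropout to 0.2: with HU-scale targets, tens of epochs and a small
network, 1e-5 cannot move the loss measurably, and 0.5 dropout in an
8-channel network removes most of its capacity. These are properties of
the desk profile definition, documented here once; the architecture,
loss, optimizer and stopping rule are identical across profiles.

Batch normalization is the default normalization and can be switched off
(`normalization = "none"`); biases are retained in all convolutions so the
"none" configuration remains well-posed. Backpropagation through the
convolution, batch-norm, dropout and residual paths is hand-written (no
deep-learning framework is involved) and is verified against central
finite differences in the test suite.

## Evaluation

Metrics are computed at the network's working resolution, inside the brain
mask eroded by a 5-pixel disk (offsets at Euclidean distance <= 2). Images
are shuffled with a fixed seed and grouped into batches (32 at clinical
scale; 8 in the desk study, where the test partition holds ~22 images);
each batch's RMSE and Spearman correlation pool the masked voxels of its
images, stratifying by brain-voxel count. The final incomplete batch is
dropped by default (equal-size stratification); a flag keeps it. Batch
sampling is without replacement. Summaries report per-comparison means
with normal-approximation 95% confidence intervals over batch values; the
per-batch table is emitted so any downstream statistics (e.g. a 2-way
ANOVA over dataset x image type) can be reproduced externally.

## Problem sizes and numerical choices

The synthetic study run by `scripts/acceptance.R` and by the end-to-end
test uses 200 scenes at 64x64 (149/29/22 after splitting), the desk
profile, at most 12 epochs with patience 3, and 8-image metric batches —
sizes chosen so the whole study runs in minutes on one CPU core while
leaving the learning-vs-physics comparison unambiguous. The 10-seed
version of the comparison runs at 32x32 with 30 scenes and 6 epochs. Other
fixed numerical choices: HU values are clamped to [-1024, 3071] at load;
median filtering uses symmetric reflection including the edge pixel;
erosion treats pixels outside the raster as background; ties in ranks
receive average ranks; the split apportionment breaks remainder ties in
partition order (train, validation, test).

## Known limitations

* The decomposition stand-in is linear; it reproduces the *role* of the
  vendor software, not its numerics.
* The iodine ratio is interpreted as the low/high enhancement ratio and
  exposed as configuration; the vendor's exact slope convention is not
  published.
* Whether the clinical lookup was built from training pixels only is not
  documented; this package builds it from the training partition only.
* The 2-D disk erosion is applied per slice; a 3-D ball across slices
  would differ near the axial extremes of a volume.
* Clinical-scale error magnitudes (e.g. RMSE in the tens of HU) are not
  reproduced by the phantom; only the ordering and direction of the
  comparisons transfer.
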