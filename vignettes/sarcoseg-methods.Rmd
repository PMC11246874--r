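---
title: "Multi-modal sarcoma segmentation: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal sarcoma segmentation: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Soft-tissue sarcoma of the thigh is routinely imaged with several MRI pulse
sequences of complementary contrast: the tumor is hypointense relative to
muscle on T1-weighted images and hyperintense on T2-weighted and STIR
images.  A clinician reads all modalities jointly; a segmentation model
should do the same.  `sarcoseg` implements an end-to-end framework for this
task: standardized preprocessing of co-registered multi-modal volumes, a
multi-encoder U-Net whose per-modality features are merged by an
attention-weighted fusion block, a masking-based self-supervised
pretraining stage for the modality encoders, and a segmentation evaluation
suite.  Because clinical sarcoma cohorts are small and rarely shareable,
the package also ships a seeded synthetic phantom cohort generator so that
every downstream stage is testable offline.

All network layers (convolutions, pooling, transposed convolutions,
normalization, the attention gates, Adam) are implemented directly in the
package on BLAS matrix operations, with hand-derived backward passes; there
is no deep-learning framework dependency.

## Preprocessing pipeline

The pipeline mirrors standard clinical-image preparation and is applied in
a fixed order per patient:

1. **Resampling** (`resample_volume`).  Each modality volume is
   interpolated onto a 1 mm isotropic grid with a 512 x 512 plane.  Both
   grids are treated as point lattices anchored at the same origin, with
   the endpoint-preserving count `n_out = round((n_in - 1) s_in / s_out) + 1`;
   this makes the first and last input slices exact fixed points and is
   directly unit-testable.  Images use linear interpolation (exact for
   intensity fields affine in physical coordinates); label masks use
   nearest-neighbour (no new intensity values).  When the interpolated
   plane is not 512 x 512 it is symmetrically center-cropped or zero-padded;
   the two operations commute with the rest of the pipeline and the pad
   offset is tracked so annotations stay aligned.
2. **Trimmed min-max normalization** (`trimmed_minmax_normalize`).  MRI
   signal intensity is not calibrated across scanners, so each scan plane
   is rescaled to [0, 1] with bounds at its own 5th and 95th intensity
   percentiles (linear-interpolation percentile convention, pinned by an
   oracle test), and values beyond the bounds are clipped.  The transform
   is invariant under positive affine rescaling of the input, which is the
   property that makes slices comparable across acquisitions.
   Normalization is per-slice and per-modality, computed on the full
   standardized plane before cropping.
3. **Annotations** (`box_annotation`, `box_to_mask`).  The ground truth is
   a rectangular marker box per scan plane, shared by all modalities of
   that plane; its filled rectangle is the training mask.  Coordinates are
   0-based, half-open, x = column / y = row — stated in the manifest
   sidecar to remove ambiguity.
4. **Tumor-centered cropping** (`crop_around_box`).  A 256 x 256 window is
   centred on the box and translated the minimum distance needed to stay
   inside the plane, so every annotated pixel is kept and the window never
   reads outside the image.
5. **Central slices** (`central_slices`).  The 64 middle scan planes of
   each sequence are retained, the same planes for every modality.

`build_dataset` orchestrates these stages and writes one NIfTI stack per
patient and modality plus a rectangle mask stack, bound together by a
manifest CSV (one row per patient and slice, with the three modality paths
and the crop-local box) and a JSON parameter sidecar.  Operationally the
central slices are selected before cropping: cropping needs a box, and
boxes exist for annotated planes; the result is identical because
normalization and cropping are per-plane operations.

## The synthetic phantom cohort

`phantom_params` / `generate_cohort` emulate the structure of a thigh MRI
cohort: per subject three co-registered modality volumes over one shared
anatomy — a cylindrical muscle compartment, an off-centre bone cylinder and
a single ellipsoidal tumor — with per-modality tissue means following the
clinical contrast ordering (tumor < muscle on the T1-like modality,
tumor > muscle on the T2- and STIR-like ones; a contrast table violating
this is rejected), additive Gaussian noise, and anisotropic native spacing
(default 6 mm slice gap vs 1.6 mm in-plane) so resampling is genuinely
exercised.  Ground truth is exact by construction: the mask is the
voxelization of the analytic ellipsoid, and per-slice boxes are its tight
bounding rectangles, recomputed on the 1 mm annotation grid by
nearest-neighbour resampling of the mask.

Deliberate idealizations: Gaussian rather than Rician noise (the noise
model is a knob, not a claim); one tumor per subject; no bias fields or
partial-volume effects; and a tumor elongated along the slice axis, with
its centre drawn from the central third of that axis and its half-length
inflated when needed, so that every one of the 64 retained planes carries
a box — the downstream contract that clinical data meets by having been
annotated. Passing tests on the phantom therefore demonstrate the
correctness of the pipeline's arithmetic, the trainability of the
architectures and the determinism of the protocol — not clinical-grade
segmentation accuracy.  Per-subject seeds are derived from the master seed
and recorded, so cohorts are bit-reproducible.

## Architectures

Three variants share one backbone (`model_config`): four encoder layers of
two 3 x 3 convolutions with channels doubling from `base_channels`
(64 -> 512 at the default) and 2 x 2 max pooling; a two-convolution
bottleneck at 16 x `base_channels` channels; a decoder of 2 x 2 transposed
convolutions (halving channels) and two 3 x 3 convolutions per layer with
skip connections; and a 1 x 1 convolution + per-pixel softmax head with two
classes.

* `sunet` — single encoder over the channel-stacked modalities, plain
  skips: the baseline U-Net.
* `munet` — one encoder per modality, skips and bottleneck input formed by
  plain channel concatenation.
* `ours` — one encoder per modality with **attention-weighted fusion** at
  every skip level and at the bottleneck input.

The fusion block concatenates the M modality features along channels and
computes `F_f = F_c + F_s`, where `F_c` re-weights channels by
`sigmoid(W2 relu(W1 z))` on the globally average-pooled channel vector `z`
(reduction ratio fixed at 2 by the stated weight shapes; no biases), and
`F_s` re-weights positions by `sigmoid(p + q)` with `q` a learned 1 x 1
projection across channels and `p` the parameter-free channel-wise max.
Both gates lie strictly in (0, 1), so `F_c` and `F_s` never exceed the
input in magnitude and `F_f` is bounded by twice the input.  One subtlety:
zeroing the gate weights neutralizes `q` but not `p`, so the fusion reduces
to the identity only where the channel max is zero; the tests exercise
exactly that configuration.

Design choices made where the architecture description left room:

* The bottleneck input is the fusion (or concatenation) of the M pooled
  layer-4 features — the only shape-consistent reading — followed by two
  3 x 3 convolutions at 16 x `base_channels` channels, continuing the
  doubling pattern.
* Skip fusion output is concatenated with the upsampled decoder feature
  and reduced back to the level's channel count by the decoder's two
  convolutions.
* Upsampling is a 2 x 2 stride-2 transposed convolution.
* A per-channel plane normalization (instance normalization: each channel
  standardized over its spatial plane, then an affine with learned scale
  and shift) follows every convolution by default (`use_norm`); gradients
  are accumulated per sample, which is what makes the per-sample variant
  the consistent choice.
* Optional identity shortcuts around each double-convolution
  (`residual_blocks`, default off; a 1 x 1 projection bridges channel
  mismatches).
* Initialization is Kaiming-uniform with zero biases, fixed by the build
  seed; the parameter count is a pure function of the configuration.

## Self-supervised pretraining

`pretrain_encoder` strengthens one modality's encoder before supervised
training.  Two branches share a single parameter set: the clean slice runs
through the full single-encoder U-Net (features `F` = flattened deepest
pooled encoder activation, plus a segmentation prediction); a corrupted
copy — a 30 x 30 patch hidden at a uniformly drawn tumor-boundary pixel
(4-adjacency boundary, window clamped inside the slice, fill value 0 = the
post-normalization background level, one fresh patch per step) — runs
through the encoder only, giving `G`.  The loss is

    L = (1 - cos(F, G)) + DiceLoss(prediction, truth)

The cosine term as a raw similarity would be *minimized* by making the two
feature vectors disagree, the opposite of the stated goal of
corruption-robust features, so the default trains on `1 - cos`
(`mode = "literal_cos"` preserves the printed form for fidelity
experiments).  The Dice term is the negative soft Dice overlap
`-2 sum(y_p y_t) / (sum(y_p) + sum(y_t))`, a value in [-1, 0], smoothed
with `eps = 1e-5` on numerator and denominator so the empty-empty case is
-1; the masked branch contributes no Dice term.  `transfer_weights` then
copies each pretrained encoder into the corresponding path of the
multi-encoder model, verifying every tensor after the copy.

## Training protocol and evaluation

`train_config` encodes the supervised protocol: Adam at learning rate 1e-5,
at most 100 epochs, early stopping after 10 epochs without validation
improvement, batch size 4 (unstated in the protocol; a config default), and
an 80/20 patient-level split (`patient_split`, all slices of a patient on
one side, `round(0.8 N)` training patients).  The validation set for early
stopping is carved from the training patients (10%) since the protocol
references validation loss without naming a set.  The "best" epoch is the
first strict minimum of validation loss; the stopping rule is a pure
function (`epochs since best >= patience`) exercised directly on synthetic
loss traces in the tests.  The supervised loss is the same soft Dice loss
as in pretraining (the protocol does not print a supervised loss; using
one objective throughout is the consistent choice), with an optional
pixelwise cross-entropy term behind `ce_weight`.

Evaluation (`evaluate_models`) scores the argmax segmentation of each test
slice with accuracy, Dice = 2TP/(2TP+FN+FP), sensitivity = TP/(TP+FN),
specificity = TN/(TN+FP), and the 95th-percentile Hausdorff distance
between foreground coordinate sets (Euclidean, scaled by pixel spacing and
reported in mm; percentile 100 gives the classical distance).  Two of the
printed source formulas for sensitivity and specificity contain typos that
can exceed 1 or mix prediction classes; the standard forms above are
implemented, matching the [0, 1] ranges of reported values.  Slice metrics
with empty denominators or empty masks are undefined: they are excluded
from the mean and counted in the report footer rather than silently
imputed.  Metrics are averaged over test slices (aggregation level is
unstated in the source; a per-patient breakdown is also emitted).

## Numerical choices

* Convolution, pooling, transposed convolution and normalization kernels
  are compiled (Rcpp/RcppArmadillo) and reduce to BLAS products; the
  convolution GEMMs run in single precision by default — the deep-learning
  standard, and a 2x saving on the memory traffic that dominates — while
  `options(sarcoseg.conv_precision = "double")` switches to a
  double-precision path used by the finite-difference gradient checks.
  All backward passes are verified against finite differences, and the
  attention algebra against dense-loop oracles at 1e-6.
* Percentiles everywhere use the linear-interpolation convention
  (`quantile` type 7), pinned in one helper.
* Max-pool and channel-max ties break toward the first candidate in a
  fixed offset order; argmax predictions break probability ties toward
  background.
* Degenerate inputs fail fast: non-finite voxels are rejected at volume
  construction, constant slices at normalization, empty masks at
  corruption and Hausdorff computation.
* Every stochastic step (phantom geometry and noise, weight
  initialization, batch order, patch placement, splits) draws from R's
  RNG under an explicit seed, and seeded runs are bit-reproducible; RNG
  state is saved and restored so library calls do not disturb the caller.

## Problem sizes used by the tests

The test-suite and the acceptance script run the full pipeline at reduced
phantom geometry (native volumes of 10 x 80 x 80 voxels at 8 x 3 x 3 mm,
which still resample to the standard 1 mm / 512-plane / 256-crop / 64-slice
layout), train the attention-fusion variant at `base_channels = 16` on 8
pipeline slices with Adam at 1e-3 (a smoke-test rate; 1e-5 remains the
protocol default), and pretrain encoders at `base_channels = 4`.  These
sizes were chosen as the smallest at which each claim under test is
non-trivial: the structural counting contract (45 x 3 x 64 = 8,640 slice
images) is exercised at full cohort width, while training checks
demonstrate optimization behaviour (loss decrease, overfitting capacity,
seeded determinism), not clinical accuracy.

## Known limitations

* The 2D, slice-wise formulation ignores through-plane context by design.
* Rectangle ground truth means reported Dice reflects agreement with
  boxes, not with voxel-precise tumor outlines.
* The phantom's geometric simplicity makes segmentation easier than
  clinical data; phantom metrics are pipeline diagnostics, not performance
  claims.
* Batch normalization with cross-sample statistics is not implemented; the
  normalization layer is per-sample by construction.
* DICOM support covers uncompressed explicit-VR little-endian series (the
  common MR export); compressed transfer syntaxes are rejected.
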