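---
title: "Two-stage pose regression for automatic C-arm positioning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage pose regression for automatic C-arm positioning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(carmpose)
```

## The problem

Intraoperative quality control in orthopedic and trauma surgery relies on
anatomy-specific *standard projections* — reference fluoroscopic views (AP,
lateral) in which implant position and fracture reduction can be judged.
Acquiring them with a mobile C-arm is a manual trial-and-error process:
the operator repositions the device and re-shoots until the view is right,
at a cost in time and radiation dose. `carmpose` implements a learning-based
alternative: a convolutional regressor predicts, directly from a single
projection image, the 5 degree-of-freedom update that moves the C-arm to the
standard pose, and a second, finer regressor polishes the result after one
repositioning.

Because annotated clinical fluoroscopy with known pose labels essentially
does not exist, the entire approach is trained *in silico*: 3D attenuation
volumes are forward-projected into fluoroscopy-like images with exactly
known pose labels. This package supplies every stage of that pipeline —
phantom generation, ray-casting projection, pose sampling and augmentation,
the CNN regressors, and the evaluation harness — so the whole method runs
as a self-contained parameter-recovery study on one desktop CPU.

## The 5-DoF C-arm pose model

A pose is `(alpha, beta, gamma, tx, ty)`:

* `alpha` — orbital rotation (LAO), degrees, rotation within the C gantry
  plane;
* `beta` — angular rotation (CRA), degrees, rotation perpendicular to the
  gantry plane;
* `gamma` — image rotation in the detector plane, degrees;
* `tx`, `ty` — detector-plane translation, millimetres.

Translation along the beam is deliberately excluded: it only rescales the
image, the regressors are trained scale-invariant, and in practice the
detector is positioned as close to the patient as possible. The principal
ray of a pose is
$\nu = [\sin\alpha,\; -\cos\alpha\,\sin\beta,\; \cos\alpha\,\cos\beta]^T$,
and the headline accuracy metric is the angle
$d\theta = \arccos(\nu \cdot \hat\nu)$ between the true and estimated rays.
In-plane error uses the circular distance
$d\gamma = \min(|\hat\gamma-\gamma|, 360-|\hat\gamma-\gamma|)$ and
translation error the Euclidean distance $dc$.

The full rotation is composed as `Rx(beta) %*% Ry(alpha) %*% Rz(gamma)`.
This order is the unique (up to equivalent conventions) composition whose
rotated z axis reproduces the printed $\nu$ formula for every `gamma`; the
test suite pins this identity on a thousand random poses. Dot products are
clamped to $[-1, 1]$ before `acos` so floating-point rounding can never
produce `NaN`. Angles are stored in degrees throughout (conversions to
radians happen only inside trigonometric calls), translations in
millimetres.

Repositioning applies a predicted update by *subtracting* its parameters
from the current pose. Poses compose additively in this parametrization;
the detector translation of an update is interpreted in the current image
frame, which is exactly the frame the network's translation label lives in.
For paired anatomies the opposite laterality is handled by mirroring:
horizontal image flip plus sign flips of `alpha`, `gamma` and `tx` — a map
that is its own inverse.

## Phantoms instead of a CT cohort

Training such a system at clinical scale requires dozens to hundreds of
annotated CT volumes, which are not redistributable. The scientific claims
under test here —
that pose parameters can be recovered from projections, and that a
two-stage coarse/fine split beats one-shot and iterated-coarse
alternatives — are geometric and learning-theoretic rather than
anatomical. The phantom factory therefore generates parametric femur-like
and vertebra-like subjects with controlled inter-subject variation:

* **Femur**: a cortical shaft *tube* with a fatty-marrow cavity and a
  posterior ridge (linea aspera), an angled neck (neck-shaft angle 127° ±
  7° across subjects) with 15° ± 7° anteversion, a spherical head with
  trabecular interior, and greater/lesser trochanters — the landmark set a
  surgeon actually uses to read orientation. All solids sit in a
  soft-tissue ellipsoid so projections are not binary masks.
* **Vertebra**: an elliptic-cylinder body with a cancellous core, spinous
  and transverse processes, in a tissue ellipsoid.

Two phantom-design choices deserve emphasis because they are *load-bearing*
for pose recovery. First, the neck anteversion breaks the front-back mirror
symmetry that a planar shaft-neck-head construction would have; under
parallel projection a mirror-symmetric object makes opposite oblique views
(`(alpha, beta)` vs `(-alpha, -beta)`) indistinguishable up to an image
flip, and early experiments with a planar phantom showed exactly this
degeneracy as an error floor. Second, the cortical-shell construction
produces the bright tangent-edge pairs characteristic of real radiographs,
which carry far sharper orientation information than the soft silhouette
of a solid rod.

Attenuation defaults approximate fluoroscopic energies: cortical bone
0.055/mm, soft tissue 0.020/mm, with trabecular bone and marrow
interpolated between them so that setting `bone_mu = tissue_mu` collapses
the skeleton to zero contrast (a property the tests exploit). Subject
variation multiplies overall size by U(0.85, 1.15) and densities by ±10-15%.

Each subject carries a *reference standard pose*: the anatomy inside the
volume is rigidly displaced by a small random rotation (sd 3°, clamped at
10°) and offset (sd 3 mm), emulating the inter-subject / inter-rater
variability of expert-defined standard planes (independent raters disagree
by several degrees even on coupled plane definitions), and
the standard pose records that displacement so that projecting *at* the
standard pose reproduces the canonical view. Cohorts split 60/20/20 into
train/validation/test by subject.

Default grids are 96³ voxels at 2 mm spacing; everything is deterministic
given the cohort seed.

## The projector

`project()` casts one ray per detector pixel from the X-ray source through
the volume and accumulates attenuation with trilinear interpolation at a
fixed step (default: half the smallest voxel spacing; the desk benchmark
uses one voxel spacing), midpoint rule, zero attenuation outside the grid.
Geometry follows a Cios Spin-class device: 300 mm square detector,
source-detector distance 1164 mm, isocenter midway (582 mm), so objects at
the isocenter appear at 2x magnification. The projector is monoenergetic:
no spectral attenuation, scatter, detector noise or collimation. The
learning problem needs geometrically consistent, contrast-plausible images,
not dosimetric fidelity, and every geometric property of the projector is
pinned by tests against an independent dense-quadrature oracle (per-pixel
agreement within 1% of dynamic range on random volumes and poses).

Rays are clipped to the bounding box of the nonzero voxels, and interior
segments take a branch-free trilinear path, which makes a 72-128 px render
of a 96³ phantom a ~5-15 ms operation — cheap enough to re-render
thousands of training poses and to run simulation-in-the-loop evaluation.

Beer-Lambert closure: `to_intensity()` maps line integrals to intensities
$I = I_0 e^{-\int\mu\,dl}$ and `neg_log()` inverts it exactly, so the
preprocessing round-trip is the identity to 1e-9.

## Training data: sampling, augmentation, preprocessing

The coarse stage samples the full grid `alpha, beta in [-30, 30]°` in 3°
steps (441 poses) around each subject's standard pose; the fine stage
samples `alpha, beta ~ N(0, (30/2.576)²)` so that the coarse region is
covered with 99% confidence (2.576 is the two-sided 99% normal quantile and
is computed, not hard-coded, so a different `coarse_range` propagates).
In-plane rotation is uniform on (-180, 180] for the coarse stage and
follows the same 99%-Gaussian for the fine stage; translations are uniform
on `[-50, 50]² mm`.

Rotation and translation are *augmentations*: each pose is rendered once
(gamma = 0, t = 0) and the in-plane rotation is emulated by image rotation,
the translation by shifting the crop window — one ray cast serves every
augmented sample of a pose. The geometric chain (rotation about the centre
composed with the shifted crop) is a single fused bilinear resample, then
the image is preprocessed (negative log to the line-integral domain, then
per-image min-max normalization to [0, 1]), then scale augmentation
`s ~ U(0.8, 1)` (zoom-ins are excluded: a shorter source-anatomy distance
means a smaller field of view and a higher dose, which is not clinical
practice) and mean-preserving contrast augmentation
`p <- (p - mu) * c + mu`, `c ~ U(0.75, 1.25)`, with a final clip to [0, 1].

Two orders deserve a note. First, the photometric augmentations (scale,
contrast) act on the *normalized network input*, matching their role as
online training augmentations; applying image-wide contrast in the raw
intensity domain can push pixels negative, and the subsequent log transform
then destroys the normalization. Second, preprocessing applies the negative
log *before* min-max normalization — the reverse order maps the darkest
pixel to zero intensity whose negative log is infinite, so it admits no
exact implementation.

A dataset can store either baked augmented samples (`store = "final"`, used
for serialization and fixed-dataset workflows) or the raw projections
(`store = "projection"`), in which case `train_regressor()` draws rotation,
translation, scale and contrast *fresh for every batch* from the same laws
(online augmentation). Online augmentation is the preferred training mode
and the default in the benchmark: with baked augmentations the network
memorizes the finite augmented set within a few epochs (train loss falls,
validation stalls), while with online draws train and validation loss track
each other closely.

The network input covers `final_size * sim_fov / sim_resolution` detector
millimetres (200 mm at the desk defaults — wide enough that the anatomy
stays mostly in view under ±50 mm translations at 2x magnification) and the
deployment path (`make_input_image()`: render at the physical pose with
gamma and t applied in the projector, centre-crop, preprocess) covers the
identical field of view; a test asserts train/deploy image agreement for
matched poses.

## The regressors

Both stages share one architecture: four convolutional blocks (3x3
kernels, batch normalization after every convolution, ReLU after the last
convolution of each block, stride-2 downsampling per block) followed by
three fully connected layers. The coarse head has six outputs — normalized
`alpha`, `beta`, the `(cos gamma, sin gamma)` pair, normalized `tx`, `ty` —
because regressing the in-plane angle through its sine and cosine keeps the
loss continuous across the ±180° wrap; the angle is recovered with the
normalized `atan2`, which is invariant to any positive rescaling of the
pair. The fine head regresses `gamma` directly (five outputs); its angular
law is narrow, so circularity is not an issue. Targets are range-normalized
to [-1, 1]: coarse `alpha`, `beta` by the 30° capture range, translations
by 50 mm, fine rotations by the 3-sigma bound of their Gaussian law
(~34.9°) since the untruncated law occasionally exceeds the nominal range.

Losses are computed in label units (degrees / millimetres). The coarse
stage uses the weighted L2 loss — squared errors on `alpha`, `beta`
(degrees), on the sin/cos channels, plus $w^2$ times squared translation
errors with $w = \pi/180$ — and the fine stage the analogous weighted L1
loss with weight $w$ on translations. $w$ equates one millimetre with one
degree expressed in radians. Batch reduction is the mean.

There is no deep-learning framework on CRAN/Bioconductor suitable for this
package's constraints, so the engine (im2col + GEMM convolutions, batch
norm, backprop, Adam) is implemented in RcppArmadillo. Two engineering
details matter for correctness:

* **Batch-norm recalibration.** After training, inference-mode batch-norm
  statistics are re-estimated as exact aggregate moments of the pre-norm
  activations over a large training sample. Momentum-based running averages
  lag the fast weight updates of short schedules and can misstate the
  statistics badly enough to erase the trained accuracy.
* **Weighted-loss/encoding consistency.** The C++ training loss operates on
  normalized targets with per-output weights chosen so that it equals the
  label-unit R losses exactly; a test asserts the identity.

Training is Adam, batch size 64, with the weights of the best-validation
epoch kept. The reference recipe is learning rate 1e-4 for 1500 epochs of
50 batches; the desk schedule (below) uses far fewer steps, and for such
short schedules an exponentially decaying rate (1e-3 down to 1e-4) reaches
a given loss in roughly half the steps of the flat reference rate in our
measurements. Model selection, initialization and batch sampling are all
seed-deterministic.

## Two-stage inference and evaluation

`two_stage_predict()` acquires an image at the initial pose, applies the
coarse update, re-acquires, applies the fine update. During evaluation the
"device" is the projector itself (simulation in the loop). The harness
draws initial poses per test subject from the coarse law (random grid
vertex, uniform in-plane rotation, uniform translation — 25 per subject by
default), runs the two-stage pipeline and the *iterated-coarse* baseline
(the coarse network applied twice; the minimal reading of iterating one
network), and reports all five error metrics per stage; the two-stage
`coarse` row doubles as the single-prediction baseline. Aggregates are
recomputable from the per-sample rows, everything is seeded, and
`autoplot()` shows the per-metric error distributions across stages.

## Desk-scale benchmark and its problem sizes

`run_recovery_benchmark()` is the package's end-to-end experiment and the
basis of the acceptance script: a 30-subject femur cohort (18 train / 6
validation / 6 test), 48 px network inputs over a 200 mm field of view
rendered at 72 px, ray step one voxel spacing, online augmentation,
channels (16, 32, 64, 128) with FC widths (256, 128), 4250 coarse and 1700
fine Adam steps with the decaying schedule, 25 evaluation draws per test
subject. These sizes were chosen so the whole study — cohort, rendering,
both trainings, evaluation — completes in roughly a quarter of an hour on
one CPU core.

What passing at this scale shows — and what it does not: the study
exercises every component of the method end to end and demonstrates genuine
parameter recovery on held-out subjects, but a network of this size trained
for a few thousand steps does not approach the accuracy of the full-scale
recipe (millions of parameters, 75 000 steps, 256 px inputs, real CT
anatomy). The residual angular error of the desk-scale coarse stage is
dominated by what the small network has not yet learned of
rotation-invariant pose reading, not by any ceiling of the simulation; the
single-factor ablations in our development history (no in-plane rotation
augmentation, or no translation augmentation) reach several-fold lower
validation loss at identical compute, which locates the difficulty squarely
in invariance learning. Scaling `model_config()`, `training_config()` and
`dataset_config()` upward recovers the full-scale setting; no code path
changes.

Phantom realism is similarly bounded: parametric solids with three
attenuation tiers emulate the geometry of orientation cues, not true
anatomy. Passing tests on phantoms therefore validates the machinery and
the recoverability claim, and says nothing quantitative about clinical
images — consistent with the role of this package as a simulation research
harness rather than a clinical tool.

## Numerical choices and degenerate inputs

* Dot products are clamped before `acos`; `gamma` wraps into (-180, 180]
  with the boundary mapped to +180.
* The projector errors out if the source lies inside the volume grid, and
  the step size must not exceed the smallest voxel spacing.
* `recover_gamma(0, 0)` is an error (undefined angle), not a silent 0.
* Non-positive intensities entering `neg_log()` are clamped to the smallest
  positive pixel with a warning; a constant image preprocesses to all
  zeros.
* Translation crops that leave the rendered region pad with edge values; a
  warning fires only when the overshoot exceeds half a pixel.
* The fine sampling law is untruncated — truncating it would break its
  defining 99%-coverage property — so fine labels may rarely leave [-1, 1];
  the L1 loss is unaffected.
* Encoding a coarse pose outside the capture range is an error; during
  inference, an out-of-range *initial* pose is flagged but still processed
  (the device cannot know the true offset).

## Known limitations

* Monoenergetic projector: no spectral effects, scatter, or detector
  noise; contrast augmentation is a crude stand-in for exposure variation.
* Additive 5-DoF pose composition: exact for the parameter conventions
  used here, but it identifies detector-frame translations across a gamma
  change, which leaves a small (few-mm at the defaults) residual when the
  standard pose itself carries a detector offset.
* The real-device adapter is an interface contract only (any function
  mapping a pose to an image); no hardware control is included.
* Vertebra phantoms are provided and tested for generation/projection, but
  the shipped benchmark trains on the femur anatomy only.
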