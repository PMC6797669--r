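---
title: "Mask-driven registration of intraoperative ultrasound: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mask-driven registration of intraoperative ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During glioma resection, the brain deforms ("brain shift") and the
pre-surgical plan loses validity. Intraoperative 3D ultrasound (iUS) can be
re-acquired at successive stages -- before the dura is opened, during
resection, and after resection -- but later acquisitions are degraded by
debris, blood and cavity artefacts, and the stages must be brought into a
common frame before they are useful. Direct intensity-based registration of
iUS pairs is fragile precisely because the appearance changes between
stages. The approach implemented here side-steps the appearance problem:
structures that stay visible throughout surgery -- the hyperechogenic sulci
and falx cerebri -- are segmented in each volume by a 3D U-Net, and the
*segmentation masks*, not the intensities, drive a mono-modal variational
registration.

`usreg` implements that pipeline end to end: domain types and I/O for
volumes, masks, landmarks and transform chains; a synthetic phantom
generator; the patch-based 3D U-Net (written from first principles on
im2col + GEMM kernels); the two-stage variational registration; and the
evaluation suite (TRE, Dice variants, capture range).

## The registration model

Given a reference mask $R$ and a template mask $T$, the method minimizes

$$ J(\varphi) = D(R, T \circ \varphi) + \alpha\, S(u), $$

where $D$ is the sum of squared differences,
$D = \tfrac12 \int (T(\varphi(x)) - R(x))^2 \, dx$, discretized on the
voxel grid with the voxel volume as quadrature weight, and $S$ is the
linear-elastic potential of the displacement $u$,

$$ S(u) = \int \frac{\mu}{4} \sum_{j,k}
   (\partial_j u_k + \partial_k u_j)^2
   + \frac{\lambda}{2} (\nabla\!\cdot u)^2 \, dx , $$

discretized with central differences in the interior and one-sided
differences at the borders (Neumann handling). Everything follows the
discretize-then-optimize paradigm: the functional is fixed on a grid and
handed to a limited-memory BFGS optimizer with Armijo backtracking.

Two stages run in sequence:

1. **Parametric.** A translation (3 parameters), then a full rigid
   transform (6 parameters), optimized on SSD alone at pyramid level 1
   (one level coarser than native), starting from the tracker-provided
   initial guess when one exists. The translation is warm-started one
   further level coarser (level 2) when the grid allows it; without the
   warm start, initial misalignments of several millimetres can lock one
   sheet onto a *neighbouring* sheet (a false SSD minimum), and the rigid
   stage then compounds the error. Rotations are intrinsic XYZ Euler
   angles about the reference volume's world center, which decouples the
   translation and rotation parameters.
2. **Nonparametric.** The dense displacement $u$ is solved coarse-to-fine
   at pyramid levels 3, 2, 1, prolongated between levels by trilinear
   interpolation (displacements are stored in millimetres, so no rescaling
   is needed). $u$ is expressed *relative to* the rigid initializer and
   only $u$ is regularized: bulk rigid motion costs nothing, as it should.

The returned chain maps reference coordinates to template coordinates and
is stored as a single dense field holding the total displacement (rigid
initializer folded in). A sequential chain `[rigid, field]` would evaluate
the field at rigidly-moved points -- not where it was solved -- so folding
keeps chain application exact; the rigid stage remains separately
available for the stage-wise error columns.

### Mask softening

Binary masks have zero intensity gradient almost everywhere, which leaves
a gradient-based optimizer without a descent direction. Registration
therefore consumes Gaussian-softened masks (`sigma_soften`, default 1.5
voxels); when the network's probability output is supplied instead, it is
used as-is. Softening only widens the attraction basin; the minimizer of
the softened problem coincides with the aligned configuration.

### Stopping criteria

The four tolerances (minimal progress, minimal gradient, relative
gradient, minimal step length) are all 0.001, with at most 100 iterations
per stage and level. Progress, step and absolute-gradient indicate
convergence only when they hold *jointly*; the relative gradient and the
iteration cap stop on their own. The joint form matters: a single slow
iteration while traversing a flat valley satisfies the progress tolerance
alone, and stopping there leaves the translation stage far from its
minimum (we observed exactly this failure before adopting the joint
rule -- it is also the convention of the standard variational registration
toolkits this formulation follows).

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 0.01 | -- | weight of the elastic term against the mm$^3$-scaled SSD |
| `mu`, `lambda` | 1, 0 | -- | Lamé parameters: pure shear penalty, no extra volumetric term |
| `sigma_soften` | 1.5 | voxels | mask softening bandwidth |
| `parametric_level` | 1 | -- | pyramid level of the rigid stage |
| `nonparametric_levels` | 3→1 | -- | coarse-to-fine schedule of the elastic stage |

`alpha` was calibrated on the synthetic-field recovery study (sweeping
0.3 down to 0.003): large values visibly over-smooth (the data term cannot
pull sheets onto their counterparts), very small values let the field
chase speckle-scale mask detail. 0.01 sits on the flat part of the
recovery curve and was frozen before the acceptance tests were written.
On real clinical masks, whose structures are coarser than the phantom's,
larger values (0.03--0.1) are reasonable first choices; the parameter is
exposed in `reg_config()`.

## The segmentation network

The segmenter is the original 3D U-Net scaled down, with two deliberate
modifications: analysis and synthesis paths have **two resolution steps**,
and a **dropout of 0.4** precedes each convolution of the synthesis path.
Channels start at 16 and double per step; each level applies two
3×3×3 convolution + instance-norm + ReLU blocks; downsampling is 2×2×2
max-pooling, upsampling a 2×2×2 stride-2 transposed convolution with skip
concatenation; a 1×1×1 convolution and sigmoid produce the voxel-wise
probability. The loss is voxel-wise binary cross-entropy (soft-Dice
available by flag), optimized by Adam at learning rate 0.001.

Training is patch-based: tiles of (30,30,30) core voxels with an (8,8,8)
context border per side, batches of 15, and model selection by the best
mean Jaccard index over 75 validation patches evaluated every 100
iterations. The arithmetic detail: 30 + 2·8 = 46 is not divisible by
2² = 4, so the input tile is mirror-extended to the next multiple of
2^steps (46 → 48, one extra voxel per side); the label and the stitched
prediction always live on the 30³ core. Patch centers are drawn 50% from
mask voxels: the sheets cover only a small fraction of the volume and
unbalanced sampling stalls training. Inputs are standardized per volume
(zero mean, unit variance). All randomness (initialization, sampling,
dropout) flows from one seed, so runs are bit-reproducible on a fixed
BLAS.

Because no deep-learning runtime is available to R here, the network --
forward, backward, Adam -- is implemented in the package itself on
im2col + GEMM kernels (Rcpp/RcppArmadillo). This keeps the training loop
deterministic and dependency-free; it is not a performance-competitive
trainer, which is irrelevant at the patch sizes involved.

## The synthetic phantom

Desk-scale development needs volumes with known ground truth. The phantom
emulates exactly the features the method relies on, and nothing more:

* **Bright sheets on speckle.** Sheets are level sets of smooth random
  low-order height functions (slope + two sinusoidal terms) swept through
  the volume and thickened to 1.5 mm, alternating sweep axes so sheets
  intersect. Sheet and background means (180 vs 60 on a B-mode-like 0-255
  scale) are modulated by multiplicative right-skewed speckle (squared
  magnitude of a complex Gaussian, unit mean, blended at weight 0.3).
* **Patchy coverage.** Each sheet is kept only where a smooth random
  indicator exceeds its 30th percentile (~70% coverage). Real sulci masks
  are segment-like, not unbroken surfaces; the gaps create the rims and
  corners that anchor in-sheet motion. With unbroken smooth sheets the
  tangential component of a deformation is genuinely unobservable from
  the masks (an aperture problem -- we verified that the registration
  objective at the ground-truth deformation exceeds its value at a
  tangentially-slid solution), and no optimizer can recover it.
* **Landmarks at corners.** Landmarks are sampled on mask voxels with
  weights favouring voxels with few mask neighbours (rims, corners,
  intersections), mirroring how clinical landmarks favour deep grooves
  and corners of sulci. Sampling is without replacement and
  seed-deterministic.
* **Known deformations.** `random_smooth_field()` draws a bulk (constant)
  displacement plus three low-frequency sinusoidal modes per component and
  rescales to a prescribed peak magnitude (default 4 mm). Brain shift is
  predominantly a bulk settling of the exposed tissue with a smoother
  residual on top; a zero-mean oscillation-only field would leave nothing
  for the parametric stage to do and is not how brain shift behaves.
  `deform_phantom()` moves landmarks *exactly* through the motion and
  pulls the volume back through the exact rigid inverse (or a fixed-point
  field inverse), so deformed pairs carry exact correspondences.
* **Resection cavities.** `simulate_resection()` empties a sphere to
  background intensity, paints a bright 1.5 mm rim around it, removes the
  ground-truth mask inside -- and deliberately does *not* add the rim to
  the ground truth. Cavities are hyperechogenic confounders with no
  pre-resection counterpart; this is the phantom's analogue of the main
  failure mode on real data.

What the phantom does **not** emulate: ray-dependent shadowing and
attenuation, probe geometry, reconstruction artefacts, anatomy. Passing
the recovery studies therefore shows that the *method* (masks → variational
registration) behaves as designed under controlled conditions; it does not
certify performance on clinical data, which depends on segmentation
quality on degraded later-stage acquisitions.

## Evaluation suite

* **TRE**: Euclidean distances between chain-mapped reference landmarks
  and their order-matched counterparts; reported per case with mean, SD,
  min, max.
* **Dice and correspondence-restricted Dice**: the restricted variant
  labels the predicted mask's 26-connected components and discards those
  with no overlap (≥ 1 voxel) with the manual mask before computing Dice
  -- the right reading when the manual annotation is sparse. It is
  provably ≥ the plain Dice of the same pair.
* **Capture range**: the largest initial misalignment (in initial-mTRE
  millimetres, realized as random-direction rigid translations, 10 trials
  per offset by default) at which ≥ 80% of trials still converge, with
  every smaller offset also passing. "Converged" defaults to final mTRE
  ≤ max(1 voxel, 1.5 × the unperturbed registration's final mTRE), since
  the underlying papers give no numeric rule.

## Numerical choices and degenerate inputs

* World frame: fixed RAS, millimetres. MetaImage (LPS) headers are
  converted on read/write by flipping the first two axes. Voxel indices
  are 0-based and node-centered: world = origin + orientation · (spacing ∘ index).
* Interpolation: trilinear everywhere; out-of-domain image reads return 0
  (background), displacement fields extrapolate by their nearest-border
  value.
* Pyramid: Gaussian (σ = 1 fine voxel, replicate borders, renormalized
  kernel) then keep-every-second-node subsampling; origin preserved,
  spacing doubled; intensity mass is preserved to well under 2% per level.
* Empty masks are rejected before registration (degenerate input);
  an empty mask in `mask_stats()` yields `NA` for the inside mean rather
  than 0.
* The convergence flag reports whether any tolerance-based rule stopped
  the run (hitting the iteration cap reports `converged = FALSE`); with
  the joint stopping rule the cap is reached routinely and the flag is
  informational, while descent itself is guaranteed by the line search.
* Problem sizes used in the shipped studies: 64³ voxels at 0.5 mm for the
  registration studies (20 rigid cases, 10 deformable cases), a 48³
  phantom for the segmentation overfit check with 12³-core patches and a
  16-channel net. These sizes keep every study a desk-scale computation
  while leaving all method parameters at their defaults.

## Known limitations

* The trainer is CPU-bound and intended for capacity checks and small
  studies, not for training on clinical datasets.
* Mask-driven SSD can only constrain motion where masks carry structure;
  in regions far from any segmented sheet the recovered field is purely
  an extrapolation of the elastic prior.
* Resection cavities segmented as bright structures have no earlier-stage
  counterpart and degrade the registration that uses them; the phantom
  reproduces the confounder, the method (by design, matching its source)
  does not yet discard such components before registering.
* Rigid steps in serialized chains record the world frame
  (`world_ras`); chains produced by other tools must be converted to that
  frame before use, including any tracker-provided initial guess.
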