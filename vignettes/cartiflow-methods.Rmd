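---
title: "cartiflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cartiflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cartiflow)
```

cartiflow is a scriptable workflow for femoral knee cartilage analysis from
3D MR volumes: spatial and intensity standardization, atlas-based cartilage
segmentation by deformable registration with automatic reference selection,
cartilage morphology (thickness and volume), and relaxometry (T2 and T1rho
maps, DESS-based T2). This vignette explains the models and algorithms, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic phantoms do and do not demonstrate.

## Data model and conventions

Images are `Image3D` objects: a voxel array (x fastest), voxel spacing in
mm, a physical origin and an orthonormal direction matrix whose columns are
the axis directions. Indices are 0-based in all geometry computations; the
physical position of index $i$ is $o + D\,(s \odot i)$. `BinaryMask` is an
`Image3D` restricted to labels $\{0,1\}$; every mask resampling in the
package is nearest-neighbour so this label set is closed under warping.

The canonical anatomical frame after spatial standardization is pinned
explicitly: axis $+x$ points toward the patient's left, $+y$ posterior,
$+z$ superior, with an identity direction matrix (RAI storage order). The
convention matters because the flattening step measures angles from the
posterior direction, and because laterality mirroring flips the first axis.
Laterality is always declared per record in the image list, never inferred
from image content.

File I/O covers MetaImage (`.mha`, uncompressed, read/write; doubles for
images, 8-bit for masks so round trips are bit-exact) and DICOM series
reading (implicit/explicit VR little endian, uncompressed). DICOM slices
are ordered by the projection of ImagePositionPatient on the slice normal,
never by filename; inconsistent slice spacing beyond $10^{-3}$ mm is
rejected naming the offending slices, and multi-echo series are split by
echo time into ascending-time volumes.

## Preprocessing

Spatial standardization is pure voxel reordering (`orientToRAI`), a content
mirror for right knees (`flipLaterality`), and an origin reset; the
composite is idempotent and reorientation preserves the physical position
of every voxel exactly.

Intensity standardization runs in a fixed order -- bias-field correction,
rescaling, edge-preserving smoothing -- and never touches the geometry.

**Bias-field correction.** MR shading is modeled as a smooth multiplicative
gain. The gain is estimated in the log domain by a ridge-regularized least
squares fit of a coarse tensor polynomial (Bernstein basis, default
$4^3$ control values, i.e. a tricubic field). Two robustness choices
matter and were set after observing how a naive fit behaves:

* the fit uses only voxels above 10% of the 99th-percentile intensity
  (background carries no tissue signal and would drag the field toward the
  anatomy outline), and among those only the dominant intensity class
  (within 1.5x of the tissue median). A smooth field fitted to a single
  class cannot soak up between-class contrast, which is anatomy, not
  shading;
* the fitted log-gain is centered on the fitted voxels, clamped to
  $[\log 1/2, \log 2]$, and ridge shrinkage keeps it flat wherever the
  fitted voxels give no support. The corrected image preserves the tissue
  mean exactly.

**Rescaling** is an affine map of the robust range (percentile-clipped;
exact min/max by default, so the default is deterministic) onto a common
range, 0--100 by default.

**Smoothing** is explicit curvature flow in index space,
$\partial_t I = \kappa\,\lvert\nabla I\rvert$, with 5 iterations and a
dimensionless time step of 0.0625 by default -- the conservative 3D
stability bound; larger steps are rejected. The result is clamped to the
input range so no new extrema can appear. Curvature flow smooths within
homogeneous regions while the 50%-level position of an edge moves by less
than a voxel (a property the tests verify on a noisy step phantom).

## Registration engine

Registration is pairwise and multiresolution (Gaussian smoothing pyramid,
3 levels by default) with a random coordinate sampler over the fixed
domain (2048 samples per level by default, seeded: runs are
bit-reproducible). A `TransformChain` maps points of the *fixed* domain
into the *moving* domain -- the resampling convention -- with stages stored
coarse to fine and the finest stage applied to a point first, matching how
stages are estimated on progressively resampled images.

**Models.** `rigid` (6 parameters, rotation about the fixed-image center)
and `similarity` (adds one global log-scale) refine a single affine stage;
`bspline` adds a cubic B-spline displacement field on a control grid with
10 mm spacing (padded so every domain point has full support).

**Metrics.** Affine stages optimize mean squared difference (default),
normalized correlation, or a Parzen soft-binned mutual information (32
bins). The deformable stage always uses mean squared difference: it runs
after intensity standardization has mapped both images to a common 0--100
range, where MSD is appropriate and has a cheap analytic gradient; MI is
the default for the multimodal segmentation mode's rigid stage and NCC for
decay-series alignment, where a global intensity scaling must not bias the
fit.

**Sampling masks.** When a focus mask (femur) is supplied, metric samples
are drawn from its dilation (6 voxels by default), not from the mask
interior. This is essential, not cosmetic: bone is nearly homogeneous, so
a metric sampled only inside the femur cannot penalize over-contraction
(any transform that maps the femur into the moving bone interior looks
perfect) and the scale estimate collapses. The dilated band keeps the
anatomy boundary visible to the metric. The final deformable stage samples
from the dilated reference cartilage mask when one is given, reproducing
the coarse-then-local strategy of registering the femur first and the
cartilage second without requiring femur masks for every target.

**Optimizers.** The affine stages use Nelder-Mead with parameter scaling,
restarted once (the simplex can stall), and the similarity stage
multi-starts over the log-scale ($\pm 0.08$): with sharply discretized
boundaries the metric has shallow local minima in the scale direction.
The deformable stage uses momentum gradient descent with the step
calibrated once from the first-iteration gradient scale, so the largest
control coefficient initially moves by the configured step (0.4 mm) and
all updates decay together with the residuals. Adam-style per-coordinate
normalization was deliberately rejected: it moves flat (noise-gradient)
coefficients at full step size, which inflates the far field of the
deformation; and a gradient below a meaningful floor (relative to the
image dynamic range) terminates the fit immediately, so registering an
image to itself returns the identity.

**Failure flagging.** After optimization the metric is re-evaluated on
fresh samples at the identity and at the optimum (dropping samples that
map outside the moving volume, which are legitimate for large
displacements); a chain that ends materially worse than the identity is
returned with `@failed = TRUE` rather than discarded.

**Inversion.** Affine chains invert in closed form. Chains with a
deformable stage are decomposed as $T = A \circ R$ with $A$ the leading
affine part: $T^{-1} = R^{-1} \circ A^{-1}$, where only the small,
well-conditioned deformable remainder $R$ is inverted numerically by
fixed-point iteration ($v \leftarrow -u(y+v)$, tolerance
$0.1\,\min(\text{spacing})$, at most 50 iterations). Inverting the full
rendered chain instead is badly conditioned far from the image center
(the affine displacement grows linearly and the fixed-point map stops
being a contraction). Non-convergence (folding) triggers a warning
reporting the mean and worst residuals.

## Segmentation

**Reference selection** (`findReference`) iterates: register every image
to the current reference (rigid + similarity + B-spline), render the
displacement fields on the reference grid, average them inside the
reference femur mask, and adopt the image whose field has the smallest
mean Euclidean distance to the average. Iteration stops when two
consecutive iterations pick the same image, or after 10 iterations; ties
break to the lowest index. The femur volume is used for the comparison
because the cartilage volume alone is too small to characterize the
deformation. Failed registrations exclude that image from the iteration
with a warning.

**Atlas propagation** (`segmentCartilage`) registers the target to the
reference with the mode's model list -- intersubject: rigid + similarity +
B-spline; longitudinal: rigid + B-spline; multimodal: rigid only (with the
MI metric by default) -- inverts the chain, and warps the reference
cartilage mask onto the target geometry with nearest-neighbour
interpolation. An empty output mask or a failed registration flags the
record; quality rows with Dice below 0.6 are marked failed, a threshold
chosen because gross registration failures produce near-zero overlap while
ordinary atlas propagations sit far above it (configurable).

**Quality metrics.** Dice is $2\lvert NM \cap GT\rvert /
(\lvert NM\rvert + \lvert GT\rvert)$; two empty masks are an error, not 0.
The average surface distance extracts boundary voxels by the
6-connectivity face rule (a foreground voxel with at least one background
face neighbour; the grid border counts as background), measures Euclidean
distances between voxel centers in physical mm, and divides the two
directed sums by the total number of boundary voxels. Both are verified
against brute-force loop oracles in the tests.

## Morphology

Per-slice contours of the cartilage mask are traced along the
medial-lateral (sagittal stack) axis as 0.5-level iso-lines
(marching-squares style), giving ordered point sequences at sub-voxel
precision in physical mm. Sides are separated per slice by an algebraic
(Kasa) circle fit to all contour points: radii from the fitted center
split into an inner (bone-facing, subchondral) and outer (articular)
cluster by 1D 2-means; points whose radial margin from the cluster
midpoint is below 25% of the estimated wall thickness -- end caps and
side-connecting segments -- are trimmed from both clouds. Slices without
radial bimodality fall back to a median-radius split with a warning, and
one-voxel walls keep all points so both sides stay nonempty.

Flattening fits a circle per slice to the subchondral points, pools
centers and radii, and maps each point to
$(\theta \cdot \bar r,\ \text{slice position})$ with $\theta$ measured
from the posterior ($+y$) axis. The branch cut of the angle is placed in
the largest empty angular gap so a shell spanning the $\pm\pi$ direction
is not torn apart. Thickness is the one-sided 3D nearest-neighbour
distance from each subchondral point to the articular cloud -- thickness
values belong to the subchondral cloud for 2D mapping, and the one-sided
distance is bounded by the symmetric Hausdorff distance. Volume is the
foreground voxel count times the voxel volume, exactly.

## Relaxometry

Voxelwise mono-exponential fitting of $S(T_a) = K e^{-T_a/T_b}$
(Levenberg-Marquardt via minpack.lm) is initialized from the closed-form
log-linear solution, falling back to the peak signal and mid-range time.
$T_b$ is T2 for echo-time series and T1rho for spin-lock series. Voxels
outside the mask, below the noise floor (peak signal under 5% of the
series' 99th-percentile signal), non-convergent, or with $T_b$ outside
$(0, 200]$ ms are invalidated -- never clamped, so summary statistics are
not distorted. The log-linear fitter (`fitLinear`) is exact on noiseless
data and fast, but biased under noise because the log transform distorts
the noise distribution; the test suite quantifies this on a fixed-seed
Monte-Carlo over $T_b \in \{20, 40, 60, 80\}$ ms at 1% noise, comparing
the mean absolute bias across the grid (at these small per-condition
sample sizes the per-condition bias estimates carry Monte-Carlo noise of
the same order as the bias itself, so the grid aggregate is the
statistically meaningful comparison). Optional motion pre-alignment
rigidly registers every lower-time volume to the highest-time volume
(NCC metric), keeping the times untouched; it is off by default.

DESS-based T2 uses a linear extended-phase-graph approximation relating
the two steady-state echoes,
$$ S_2 / S_1 = \sin^2(\alpha/2)\, e^{-2 (TR - TE)/T_2}, $$
inverted in closed form per voxel. The forward model (`dessRatio`) and
the inverse (`t2FromDess`) are a single isolated, documented pair so the
approximation constant can be revised in one place; the self-consistency
tests (noiseless round trip exact to $10^{-6}$, monotonicity in the echo
ratio) pin the behaviour rather than the constant. Voxels with
$S_1 \le 0$, $S_2 \le 0$ or a ratio outside $(0, \sin^2(\alpha/2))$ are
invalid; a ratio of at least 1 everywhere is rejected as unphysical.
Map summaries report mean, population SD and voxel count over valid
in-mask voxels.

## Synthetic phantoms: what they emulate, and what they do not

`makeKneePhantom` builds a half-cylindrical "femur" with an attached
cartilage shell of exactly known wall thickness, with three intensity
levels, optional Gaussian (or Rician) noise, a smooth multiplicative gain
field, and a rigid displacement. The displacement is applied analytically
-- the membership tests are evaluated at displaced coordinates -- so the
masks remain the exact voxelization of the displaced shapes and the
analytic truths (wall, shell volume) are returned with the data. Noise
and bias touch only the intensity image, never the masks. The shell has
free axial ends (70% of the grid extent by default) so every rigid
displacement component is observable.

The five-phantom fixture cohort uses bone radii 18--22 mm with walls
1.6--2.4 mm (femoral-condyle and cartilage scale), mild Gaussian noise
($\sigma = 2$ on a 5/40/90 intensity scale, roughly 2% of the dynamic
range), and small deterministic per-phantom displacements up to about
2 mm so both the rigid and the deformable stages do real work. The shell
length scales with the bone radius, making the phantoms differ by an
approximately isotropic scaling about the middle phantom -- by
construction the radius-20 phantom is the cohort's mean shape and the
expected fixed point of the reference search.

What passing on phantoms does *not* show: the phantoms have piecewise
constant tissue, analytic geometry, no partial-volume ramps, no
fat-suppression or motion artifacts, Gaussian rather than Rician noise by
default, and far less shape variability than a patient cohort. Phantom
results validate the machinery (geometry handling, transform algebra,
metric implementations, fit correctness, determinism), not clinical
segmentation accuracy; on real cohort data the expected overlap is
substantially lower than on phantoms.

One voxelization subtlety is worth recording: when a phantom is displaced
by a non-integer number of voxels, the ground-truth mask (re-voxelized
analytic shape) is *not* a lattice translate of the reference mask, so
even a perfect transform plus nearest-neighbour warping cannot reach
Dice 1 on a thin shell. Checks that isolate rigid accuracy therefore use
integer-voxel displacements; cohort-level checks accept the re-voxelization
cost, which at 0.5 mm in-plane spacing is a few percent of Dice.

## Workflow, determinism, problem sizes

`runStage` processes the records of a plain-text image list independently,
one image per worker process, isolating per-image failures as failed
manifest rows. Every image derives its seed deterministically from the
master seed and its list position, so results are bit-identical across
reruns, batch orders and core counts; the manifest echoes the resolved
configuration and `reportDependencies()` records interpreter, package and
OS versions. The CLI (`inst/scripts/cartiflow.R`) is a thin wrapper over
these functions.

The test and acceptance problem sizes are deliberate package choices
balancing coverage against turnaround: registration-heavy checks run on a
20 x 64 x 64 cohort at (1.2, 1, 1) mm; the cohort segmentation surface
runs at full fixture resolution, 24 x 120 x 120 at (1, 0.5, 0.5) mm;
morphology recovery uses a 0.5 mm isotropic shell; relaxometry
Monte-Carlo uses 500 voxels per condition. Scaling any of these up only
tightens the same estimates.

## Known limitations

* Registration assumes the RAI-standardized frame for its B-spline grid
  (axis-aligned physical box) and computes image gradients along index
  axes; strongly oblique direction matrices should be standardized first.
* Only mono-exponential relaxometry is implemented (no multi-component
  T2, no B1 correction), and the DESS estimator is a linear approximation
  valid for ratios below $\sin^2(\alpha/2)$.
* The thickness algorithm is 3D nearest neighbour only; the `algo`
  argument is a placeholder for surface-normal or potential-field
  alternatives.
* MetaImage support is uncompressed local-data `.mha`; NIfTI and DICOM
  writing are out of scope.
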