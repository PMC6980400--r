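# cartiflow

An R workflow for open, reproducible analysis of femoral knee cartilage
from 3D magnetic resonance images. It is aimed at musculoskeletal imaging
researchers who need a scriptable, fully deterministic pipeline from raw
volumes (DICOM series or MetaImage `.mha`) to per-image tables of cartilage
morphology and relaxometry, without manual segmentation.

The workflow has three stages, each usable on its own:

1. **Preprocessing** — spatial standardization (RAI orientation, mirroring
   of right knees to left laterality, origin reset) and intensity
   standardization (multiplicative bias-field correction, rescaling to a
   common range, edge-preserving curvature-flow smoothing).
2. **Segmentation** — atlas-based propagation: the target is registered to
   a pre-segmented reference with a multiresolution rigid / similarity /
   cubic-B-spline chain, the transform is inverted, and the reference
   cartilage mask is warped onto the target with nearest-neighbour
   interpolation. The reference itself can be selected automatically by a
   convergence study: iteratively register all images to the current
   reference, average the displacement fields inside the femur, and adopt
   the image whose field is closest to the average. Quality is reported as
   the Dice similarity coefficient,
   DSC = 2|NM∩GT| / (|NM|+|GT|),
   and the average surface distance (mean boundary-to-boundary Euclidean
   distance, mm).
3. **Analysis** — cartilage thickness via per-slice sub-voxel contours,
   subchondral/articular side separation, cylinder-fit flattening
   (2D thickness maps) and 3D nearest-neighbour distances; cartilage
   volume; voxelwise relaxometry by mono-exponential fitting
   S(Tₐ) = K·exp(−Tₐ/T_b) (Levenberg–Marquardt, with a fast log-linear
   alternative, T_b = T2 or T1ρ), and DESS-based T2 from a linear
   extended-phase-graph approximation of the two steady-state echoes.

Deterministic synthetic knee phantoms (a half-cylindrical bone with a
cartilage shell of exactly known wall thickness, plus decay series and DESS
pairs with known truth) make every stage testable end to end without any
image download. See `vignettes/cartiflow-methods.Rmd` for the methods and
design notes.

## Worked example

Segment a phantom cohort member against the cohort's mean-shape reference
and quantify it:

```r
library(cartiflow)

co  <- makePhantomCohort(dim = c(20L, 64L, 64L), spacing = c(1.2, 1, 1),
                         noiseSigma = 2, seed = 1)
ref <- co[[3]]         # mean shape: bone radius 20 mm, wall 2.0 mm
tgt <- co[[5]]         # bone radius 22 mm, wall 2.4 mm, displaced

ctl <- regControl(samples = 1200, bsplineIterations = c(60, 40), seed = 11)
seg <- segmentCartilage(ref$image, ref$cartilageMask, tgt$image,
                        "intersubject", referenceFemur = ref$femurMask,
                        control = ctl)

dice(seg$mask, tgt$cartilageMask)                   # 0.93
averageSurfaceDistance(seg$mask, tgt$cartilageMask) # 0.145 mm

surf <- morphologyAnalysis(seg$mask)
morphologySummary(surf, seg$mask)
#   mean_thickness_mm sd_thickness_mm volume_mm3
# 1          2.186473       0.3917596       2940
```

The propagated mask overlaps the analytic ground-truth shell with Dice
0.93 and mean surface error 0.145 mm (about a seventh of a voxel); the
thickness estimate 2.19 mm and volume 2940 mm³ recover the phantom's true
2.4 mm wall and 3149 mm³ shell to within the voxelization error of the
coarse 1 mm grid used here. A relaxometry fit on a noisy synthetic
spin-lock series recovers the true T1ρ of 40 ms:

```r
d   <- makeDecaySeries(tb = 40, k = 100, times = c(1, 10, 30, 60),
                       sigma = 1, seed = 2)
fit <- fitExponential(d$series)
mapStatistics(fit, BinaryMask(array(1, dim(fit@tbMap)),
                              spacing = spacing(fit@tbMap)))
#    mean_ms    sd_ms n_voxels
# 1 40.07382 0.879359      200
```

Batch processing goes through `runStage()` (stages `make-fixtures`,
`preprocess`, `find-reference`, `segment`, `morphology`,
`relaxometry-fit`, `relaxometry-dess`, `evaluate`), driven by a plain-text
image list; a thin command-line wrapper is installed at
`inst/scripts/cartiflow.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/cartiflow.R", package = "cartiflow"))')" \
    make-fixtures --out fixtures --seed 1
```

Every run writes a manifest echoing the resolved configuration and the
dependency versions; results are bit-identical across reruns and worker
counts because each image derives its seed from the master seed and its
list position.

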