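Package: cartiflow
Title: Open Workflow for Femoral Knee Cartilage Morphology and Relaxometry
    from 3D MR Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An image-analysis workflow for femoral knee cartilage from 3D
    magnetic resonance images. Standardizes image volumes spatially (RAI
    orientation, laterality flip, origin reset) and in intensity (bias-field
    correction, rescaling, edge-preserving curvature-flow smoothing), segments
    femoral cartilage by atlas-based deformable registration with automatic
    reference-image selection by deformation-field convergence, and quantifies
    cartilage morphology (thickness via cylinder-unrolled flattening maps,
    volume) and relaxometry (voxelwise mono-exponential and log-linear T2/T1rho
    fitting, DESS-based T2 from a linear extended-phase-graph approximation).
    Includes MetaImage and DICOM-series readers, a multiresolution
    rigid/similarity/B-spline registration engine, segmentation-quality
    metrics (Dice coefficient, average surface distance), deterministic
    synthetic knee phantoms for end-to-end testing, and a batch workflow
    driver with per-image parallelism and run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    parallel,
    tools,
    Rcpp,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
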