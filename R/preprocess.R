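# Spatial and intensity standardization.
#
# Spatial: reorient to canonical RAI storage (pure voxel reordering), mirror
# right knees to left laterality, reset the origin to (0,0,0).
# Intensity (fixed order): bias-field correction -> rescale to a common
# range -> edge-preserving curvature-flow smoothing.

#' Preprocessing configuration
#'
#' @param rescaleRange target intensity range, default c(0, 100).
#' @param percentiles robust clipping percentiles for rescaling; the default
#'   c(0, 100) uses the exact min/max (deterministic); tighten for
#'   outlier-heavy data.
#' @param biasCorrection logical, run bias-field correction.
#' @param biasResolution control points per axis of the smooth gain field
#'   (default 4, i.e. a cubic tensor field).
#' @param smoothingIterations curvature-flow iterations (default 5).
#' @param smoothingTimestep dimensionless explicit time step; must lie in
#'   (0, 0.0625] for 3D stability (default 0.0625).
#' @return A validated list of class "PreprocessConfig".
#' @export
preprocessConfig <- function(rescaleRange = c(0, 100),
                             percentiles = c(0, 100),
                             biasCorrection = TRUE, biasResolution = 4L,
                             smoothingIterations = 5L,
                             smoothingTimestep = 0.0625) {
  stopifnot(length(rescaleRange) == 2L, rescaleRange[1] < rescaleRange[2],
            length(percentiles) == 2L, percentiles[1] < percentiles[2],
            percentiles[1] >= 0, percentiles[2] <= 100,
            smoothingIterations >= 0, biasResolution >= 2)
  if (smoothingTimestep <= 0 || smoothingTimestep > 0.0625 + 1e-12)
    stop("smoothing timestep outside the 3D stability bound (0, 0.0625]")
  structure(list(rescaleRange = rescaleRange, percentiles = percentiles,
                 biasCorrection = isTRUE(biasCorrection),
                 biasResolution = as.integer(biasResolution),
                 smoothingIterations = as.integer(smoothingIterations),
                 smoothingTimestep = smoothingTimestep),
            class = "PreprocessConfig")
}

#' Reorient an image to canonical RAI storage
#'
#' Permutes and flips the voxel axes (no resampling) so the direction matrix
#' becomes the axis-aligned identity (for axis-aligned inputs) or its closest
#' rotation. The physical position of every voxel is unchanged. The canonical
#' frame stores +x toward the patient's left, +y posterior, +z superior.
#'
#' @param image an [Image3D-class] (or [BinaryMask-class]).
#' @return The reoriented image, voxel-identical up to axis reordering.
#' @export
orientToRAI <- function(image) {
  stopifnot(is(image, "Image3D"))
  D <- image@direction
  if (!.orthonormal(D)) stop("direction matrix is not orthonormal")
  perm <- integer(3)
  sgn <- numeric(3)
  for (t in 1:3) {
    perm[t] <- which.max(abs(D[t, ]))
    sgn[t] <- sign(D[t, perm[t]])
  }
  if (length(unique(perm)) != 3L)
    stop("degenerate direction matrix: no unique axis permutation")
  if (all(perm == 1:3) && all(sgn > 0)) return(image)
  old <- geometry(image)
  vox <- aperm(image@voxels, perm)
  for (t in 1:3) {
    if (sgn[t] < 0) {
      idx <- rev(seq_len(dim(vox)[t]))
      vox <- switch(t, vox[idx, , , drop = FALSE],
                    vox[, idx, , drop = FALSE],
                    vox[, , idx, drop = FALSE])
    }
  }
  i0 <- numeric(3)
  for (t in 1:3) i0[perm[t]] <- if (sgn[t] > 0) 0 else old$dim[perm[t]] - 1
  neworg <- as.vector(indexToPhysical(old, i0))
  newdir <- D[, perm, drop = FALSE] %*% diag(sgn)
  dimnames(newdir) <- NULL
  out <- image
  out@voxels <- vox
  out@spacing <- old$spacing[perm]
  out@origin <- neworg
  out@direction <- newdir
  validObject(out)
  out
}

#' Mirror a right knee to left laterality
#'
#' For `side = "right"` the voxel array is mirrored along the left-right
#' axis (content flip; geometry untouched) so that all images share the left
#' laterality. For `side = "left"` the image is returned unchanged.
#' Laterality is always declared per record in the image list, never inferred
#' from image content.
#'
#' @param image an [Image3D-class] in RAI orientation.
#' @param side "left" or "right".
#' @return The (possibly mirrored) image.
#' @export
flipLaterality <- function(image, side) {
  stopifnot(is(image, "Image3D"))
  if (!side %in% c("left", "right"))
    stop("unknown laterality token '", side, "' (expected left or right)")
  if (max(abs(image@direction - diag(3))) > 1e-3)
    stop("flipLaterality expects an RAI-oriented image; run orientToRAI first")
  if (side == "left") return(image)
  out <- image
  out@voxels <- image@voxels[rev(seq_len(dim(image@voxels)[1])), , ,
                             drop = FALSE]
  out
}

#' Reset the image origin to (0, 0, 0)
#'
#' @param image an [Image3D-class].
#' @return The image with origin (0,0,0); voxels, spacing and direction are
#'   untouched.
#' @export
resetOrigin <- function(image) {
  stopifnot(is(image, "Image3D"))
  out <- image
  out@origin <- c(0, 0, 0)
  out
}

#' Standardize image space (orient + laterality + origin)
#'
#' Composite of [orientToRAI()], [flipLaterality()] and [resetOrigin()]; the
#' composite is idempotent for a fixed `side = "left"` re-run.
#'
#' @inheritParams flipLaterality
#' @return The spatially standardized image.
#' @export
standardizeSpace <- function(image, side = "left") {
  resetOrigin(flipLaterality(orientToRAI(image), side))
}

# Bernstein tensor basis (deg = res - 1) evaluated at normalized coords u
.bernstein_basis <- function(u, res) {
  deg <- res - 1L
  vapply(0:deg, function(i) choose(deg, i) * u^i * (1 - u)^(deg - i),
         numeric(length(u)))
}

#' Correct smooth multiplicative intensity inhomogeneity
#'
#' Estimates a smooth multiplicative bias (gain) field in the log domain by
#' least-squares fitting a coarse tensor polynomial over the foreground
#' (positive) voxels, then divides it out. The corrected image preserves the
#' foreground mean exactly and stays nonnegative. This addresses the smooth
#' B0-inhomogeneity shading typical of MR volumes.
#'
#' @param image an [Image3D-class] with nonnegative intensities.
#' @param resolution control points per axis of the gain model (default 4).
#' @param maxFitVoxels fit on at most this many (evenly strided) tissue
#'   voxels for speed.
#' @param tissueFraction voxels below this fraction of the 99th-percentile
#'   intensity are treated as background and excluded from the gain fit
#'   (they carry no tissue signal, only noise, and would otherwise drag the
#'   fitted field toward the anatomy outline).
#' @return The bias-corrected image (geometry untouched).
#' @export
correctFieldInhomogeneity <- function(image, resolution = 4L,
                                      maxFitVoxels = 20000L,
                                      tissueFraction = 0.1) {
  stopifnot(is(image, "Image3D"))
  vox <- image@voxels
  if (any(vox < 0)) stop("bias correction expects nonnegative intensities")
  if (all(vox == 0)) stop("cannot bias-correct an all-zero image")
  d <- dim(vox)
  thr <- tissueFraction * stats::quantile(vox, 0.99, names = FALSE)
  fg <- which(vox > max(thr, 0))
  if (!length(fg)) fg <- which(vox > 0)
  # restrict the fit to the dominant intensity class (within 1.5x of the
  # tissue median): a smooth gain estimated from one class cannot soak up
  # between-class contrast, which would distort anatomy instead of shading
  med <- stats::median(vox[fg])
  band <- fg[abs(log(vox[fg] / med)) < log(1.5)]
  if (length(band) >= 500L) fg <- band
  if (length(fg) > maxFitVoxels)
    fg <- fg[seq(1L, length(fg), length.out = maxFitVoxels)]
  ijk <- arrayInd(fg, d)
  u <- lapply(1:3, function(a)
    if (d[a] > 1) (ijk[, a] - 1) / (d[a] - 1) else rep(0.5, nrow(ijk)))
  res <- as.integer(resolution)
  Bx <- .bernstein_basis(u[[1]], res)
  By <- .bernstein_basis(u[[2]], res)
  Bz <- .bernstein_basis(u[[3]], res)
  X <- matrix(0, nrow(ijk), res^3)
  col <- 1L
  for (k in seq_len(res)) for (j in seq_len(res)) for (i in seq_len(res)) {
    X[, col] <- Bx[, i] * By[, j] * Bz[, k]
    col <- col + 1L
  }
  # ridge-regularized fit of the centered log intensities: shrinkage keeps
  # the field flat wherever the fitted voxels give no support (the basis is
  # otherwise unconstrained outside the tissue region)
  y <- log(vox[fg])
  yc <- y - mean(y)
  lambda <- 1e-3 * nrow(X)
  coefs <- tryCatch(
    solve(crossprod(X) + lambda * diag(ncol(X)), crossprod(X, yc)),
    error = function(e) matrix(0, ncol(X), 1))
  coefs <- as.vector(coefs)
  coefs[is.na(coefs)] <- 0
  # evaluate the fitted log-gain on the full grid (separable expansion)
  gx <- .bernstein_basis(if (d[1] > 1) (seq_len(d[1]) - 1) / (d[1] - 1)
                         else 0.5, res)
  gy <- .bernstein_basis(if (d[2] > 1) (seq_len(d[2]) - 1) / (d[2] - 1)
                         else 0.5, res)
  gz <- .bernstein_basis(if (d[3] > 1) (seq_len(d[3]) - 1) / (d[3] - 1)
                         else 0.5, res)
  logf <- array(0, d)
  col <- 1L
  for (k in seq_len(res)) for (j in seq_len(res)) for (i in seq_len(res)) {
    if (coefs[col] != 0)
      logf <- logf + coefs[col] *
        (gx[, i] %o% gy[, j] %o% gz[, k])
    col <- col + 1L
  }
  tissue <- vox > max(thr, 0)
  if (!any(tissue)) tissue <- vox > 0
  # the field is already centered on the fitted voxels; clamp to a
  # physically plausible gain range before dividing it out
  logf <- pmin(pmax(logf - mean(logf[fg]), -log(2)), log(2))
  gain <- exp(logf)
  corrected <- vox / gain
  mfin <- mean(corrected[tissue])
  morig <- mean(vox[tissue])
  if (mfin > 0) corrected <- corrected * (morig / mfin)
  out <- image
  out@voxels <- corrected
  out
}

#' Rescale intensities to a common range
#'
#' Affine map taking the robust minimum/maximum (percentile-based; exact
#' min/max by default) to `range[1]`/`range[2]`, with clipping outside.
#'
#' @param image an [Image3D-class] with at least two distinct intensities.
#' @param range target (low, high), default c(0, 100).
#' @param percentiles robust clipping percentiles, default c(0, 100).
#' @return The rescaled image.
#' @export
rescaleIntensity <- function(image, range = c(0, 100),
                             percentiles = c(0, 100)) {
  stopifnot(is(image, "Image3D"), length(range) == 2L,
            range[1] < range[2])
  vox <- image@voxels
  qs <- stats::quantile(vox, percentiles / 100, names = FALSE)
  if (qs[1] >= qs[2])
    stop("cannot rescale a constant image (undefined intensity map)")
  scaled <- (vox - qs[1]) / (qs[2] - qs[1]) * (range[2] - range[1]) + range[1]
  scaled[scaled < range[1]] <- range[1]
  scaled[scaled > range[2]] <- range[2]
  out <- image
  out@voxels <- scaled
  out
}

#' Edge-preserving smoothing by curvature flow
#'
#' Explicit curvature-flow evolution (in index space) that smooths within
#' homogeneous regions while preserving edges; the global intensity range is
#' never expanded. Zero iterations return the image unchanged.
#'
#' @param image an [Image3D-class] with finite intensities.
#' @param iterations number of explicit steps (>= 0).
#' @param timestep dimensionless step in (0, 0.0625] (3D stability bound).
#' @return The smoothed image (geometry untouched).
#' @export
smoothEdges <- function(image, iterations = 5L, timestep = 0.0625) {
  stopifnot(is(image, "Image3D"), iterations >= 0)
  if (any(!is.finite(image@voxels)))
    stop("smoothEdges expects finite intensities")
  if (timestep <= 0 || timestep > 0.0625 + 1e-12)
    stop("timestep outside the 3D stability bound (0, 0.0625]")
  if (iterations == 0L) return(image)
  d <- dim(image@voxels)
  sm <- cpp_curvature_flow(as.double(image@voxels), as.integer(d),
                           as.integer(iterations), timestep)
  out <- image
  out@voxels <- array(sm, d)
  out
}

#' Full preprocessing of one image
#'
#' Spatial standardization ([standardizeSpace()]) followed by the fixed
#' intensity pipeline: bias correction, rescaling, curvature-flow smoothing.
#' The applied step order is recorded in the `"steps"` attribute for the run
#' log.
#'
#' @param image an [Image3D-class].
#' @param side laterality token of the record ("left"/"right").
#' @param config a [preprocessConfig()] list.
#' @param intensity run the intensity pipeline (TRUE) or spatial
#'   standardization only.
#' @return The preprocessed image; attribute "steps" lists the applied
#'   operations in order.
#' @export
preprocessImage <- function(image, side = "left",
                            config = preprocessConfig(), intensity = TRUE) {
  stopifnot(inherits(config, "PreprocessConfig"))
  steps <- c("orientToRAI", "flipLaterality", "resetOrigin")
  out <- standardizeSpace(image, side)
  if (intensity) {
    if (config$biasCorrection) {
      out <- correctFieldInhomogeneity(out, config$biasResolution)
      steps <- c(steps, "correctFieldInhomogeneity")
    }
    out <- rescaleIntensity(out, config$rescaleRange, config$percentiles)
    steps <- c(steps, "rescaleIntensity")
    if (config$smoothingIterations > 0) {
      out <- smoothEdges(out, config$smoothingIterations,
                         config$smoothingTimestep)
      steps <- c(steps, "smoothEdges")
    }
  }
  attr(out, "steps") <- steps
  out
}
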