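# Pairwise multiresolution registration: rigid, similarity (rigid + global
# scale) and cubic B-spline deformable stages, driven by a random coordinate
# sampler over the fixed domain and (for the deformable stage) an
# Adam-stabilized gradient descent on a mean-squared-difference metric.
# Affine stages are optimized derivative-free (Nelder-Mead) over 6-7
# parameters on a smoothing image pyramid.

#' Registration control parameters
#'
#' Defaults: 3 pyramid levels, 2048 random samples per level, at most 500
#' affine optimizer iterations per level, 10 mm final B-spline control-grid
#' spacing. All values are logged with every run.
#'
#' @param levels pyramid levels (coarsest is smoothed/downsampled 2^(levels-1)
#'   times).
#' @param samples random coordinate samples per level.
#' @param maxIterations affine optimizer iteration cap per level.
#' @param metric "msd" (mean squared difference), "ncc" (normalized
#'   correlation) or "mi" (Parzen-binned mutual information) for the affine
#'   stages. B-spline stages always use msd (they run after intensity
#'   standardization to a common range).
#' @param mattesBins histogram bins for the mi metric.
#' @param bsplineSpacing control-point spacing (mm) of the deformable stage.
#' @param bsplineIterations Adam iterations for the deformable stage, one
#'   value per deformable level (it runs on the two finest pyramid levels).
#' @param bsplineStep Adam step size in mm.
#' @param focusDilate dilation (voxels) applied to the cartilage focus mask.
#' @param sampleDilate dilation (voxels) applied to `focusMask` before
#'   sampling so that anatomy boundaries stay visible to the metric (a mask
#'   restricted to a homogeneous interior cannot penalize over-contraction).
#' @param initCenterOfMass initialize translation from intensity centroids.
#' @param seed RNG seed for the coordinate sampler; every run with the same
#'   seed and inputs is bit-reproducible.
#' @return A list of class "RegControl".
#' @export
regControl <- function(levels = 3L, samples = 2048L, maxIterations = 500L,
                       metric = c("msd", "ncc", "mi"), mattesBins = 32L,
                       bsplineSpacing = 10, bsplineIterations = c(120L, 60L),
                       bsplineStep = 0.4, focusDilate = 3L,
                       sampleDilate = 6L,
                       initCenterOfMass = TRUE, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(levels >= 1, samples >= 16, maxIterations >= 1,
            bsplineSpacing > 0, all(bsplineIterations >= 0), bsplineStep > 0)
  structure(list(levels = as.integer(levels), samples = as.integer(samples),
                 maxIterations = as.integer(maxIterations), metric = metric,
                 mattesBins = as.integer(mattesBins),
                 bsplineSpacing = bsplineSpacing,
                 bsplineIterations = as.integer(bsplineIterations),
                 bsplineStep = bsplineStep,
                 focusDilate = as.integer(focusDilate),
                 sampleDilate = as.integer(sampleDilate),
                 initCenterOfMass = isTRUE(initCenterOfMass),
                 seed = as.integer(seed)),
            class = "RegControl")
}

.metric_code <- function(m) switch(m, msd = 0L, ncc = 1L, mi = 2L)

# Gaussian smooth (sigma voxels) + stride-2 subsample
.pyramid_down <- function(img) {
  g <- geometry(img)
  sm <- cpp_gaussian_smooth(as.double(img@voxels), as.integer(g$dim),
                            c(1, 1, 1))
  arr <- array(sm, g$dim)
  idx <- lapply(g$dim, function(n) seq(1L, n, by = 2L))
  Image3D(arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
          spacing = g$spacing * 2, origin = g$origin,
          direction = g$direction, modality = img@modality)
}

.make_pyramid <- function(img, levels) {
  out <- vector("list", levels)
  out[[levels]] <- img # finest
  if (levels > 1)
    for (l in (levels - 1):1) out[[l]] <- .pyramid_down(out[[l + 1]])
  out
}

# nearest-neighbour transfer of a mask to a pyramid level's geometry
.mask_on_level <- function(mask, levelGeom) {
  if (is.null(mask)) return(NULL)
  m <- resampleImage(mask, identityChain(levelGeom), levelGeom,
                     interp = "nearest")
  m@voxels
}

# intensity centroid in physical coordinates
.center_of_mass <- function(img) {
  v <- as.vector(img@voxels)
  v <- v - min(v)
  s <- sum(v)
  if (s <= 0) return(as.vector(indexToPhysical(img, (dim(img) - 1) / 2)))
  g <- geometry(img)
  d <- g$dim
  ix <- rep(seq_len(d[1]) - 1, times = d[2] * d[3])
  iy <- rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  com_idx <- c(sum(ix * v), sum(iy * v), sum(iz * v)) / s
  as.vector(indexToPhysical(g, com_idx))
}

.euler_matrix <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# (A, t) for parameters about center c: T(x) = s R (x - c) + c + t
.affine_from_params <- function(p, center, model) {
  R <- .euler_matrix(p[1:3])
  s <- if (model == "similarity") exp(p[7]) else 1
  A <- s * R
  t <- p[4:6] + center - as.vector(A %*% center)
  list(A = A, t = t)
}

# draw sample voxel centers + fixed values on one level
.draw_samples <- function(fixedLevel, n, maskArr = NULL) {
  g <- geometry(fixedLevel)
  total <- prod(g$dim)
  pool <- if (is.null(maskArr)) seq_len(total) else which(maskArr > 0)
  if (!length(pool)) pool <- seq_len(total)
  take <- if (length(pool) <= n) pool else sample(pool, n)
  ijk <- arrayInd(take, g$dim) - 1
  list(pts = indexToPhysical(g, ijk),
       vals = as.vector(fixedLevel@voxels)[take])
}

.metric_affine_eval <- function(movingLevel, samples, A, t, metric, bins,
                                frange, mrange) {
  g <- geometry(movingLevel)
  cpp_metric_affine(as.double(movingLevel@voxels), as.integer(g$dim),
                    as.double(g$spacing), as.double(g$origin),
                    as.double(g$direction), samples$vals, samples$pts,
                    as.double(A), as.double(t), .metric_code(metric),
                    as.integer(bins), frange, mrange)
}

# metric between paired intensity samples (used for the final/identity check)
.paired_metric <- function(fv, mv, metric, bins = 32L) {
  if (metric == "msd") return(mean((fv - mv)^2))
  if (metric == "ncc") {
    if (stats::sd(fv) == 0 || stats::sd(mv) == 0) return(1)
    return(1 - stats::cor(fv, mv)^2)
  }
  cf <- cut(fv, bins); cm <- cut(mv, bins)
  H <- table(cf, cm) / length(fv)
  pf <- rowSums(H); pm <- colSums(H)
  mi <- sum(H * log(H / outer(pf, pm)), na.rm = TRUE)
  -mi
}

#' Register a moving image to a fixed image
#'
#' Multiresolution registration with a smoothing image pyramid and a random
#' coordinate sampler. Models are applied coarse to fine; "rigid" and
#' "similarity" refine a single affine stage, "bspline" adds a cubic
#' B-spline displacement stage fitted to the affinely resampled moving image
#' with metric sampling restricted to `cartilageFocus` (dilated) when given,
#' else `focusMask`, else the whole overlap. The returned chain maps fixed-
#' domain points into the moving domain; warp masks through its inverse.
#'
#' If the optimum is worse than the identity transform the chain is returned
#' with `@failed = TRUE` rather than discarded.
#'
#' @param fixed,moving [Image3D-class] volumes with finite intensities.
#' @param models nonempty ordered subset of c("rigid", "similarity",
#'   "bspline"), coarse to fine.
#' @param focusMask optional [BinaryMask-class] on the fixed geometry
#'   restricting metric sampling (e.g. a femur mask).
#' @param cartilageFocus optional [BinaryMask-class] on the fixed geometry;
#'   the deformable stage samples from its dilation (anatomy-focused
#'   refinement).
#' @param control a [regControl()] list.
#' @return A [TransformChain-class] with `@models` recording the applied
#'   registration models and `@metric` the identity/final metric values.
#' @export
registerImages <- function(fixed, moving,
                           models = c("rigid", "similarity", "bspline"),
                           focusMask = NULL, cartilageFocus = NULL,
                           control = regControl()) {
  stopifnot(is(fixed, "Image3D"), is(moving, "Image3D"),
            inherits(control, "RegControl"))
  if (any(!is.finite(fixed@voxels)) || any(!is.finite(moving@voxels)))
    stop("registration requires finite image intensities")
  models <- match.arg(models, c("rigid", "similarity", "bspline"),
                      several.ok = TRUE)
  if (!length(models)) stop("model list must be nonempty")
  ord <- match(models, c("rigid", "similarity", "bspline"))
  if (is.unsorted(ord))
    stop("models must be ordered coarse to fine (rigid < similarity < ",
         "bspline)")
  if (!is.null(focusMask) &&
      !sameGeometry(geometry(focusMask), geometry(fixed)))
    .stop_geometry_mismatch("fixed image and focus mask")

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(control$seed)

  fgeom <- geometry(fixed)
  fpyr <- .make_pyramid(fixed, control$levels)
  mpyr <- .make_pyramid(moving, control$levels)
  frange <- range(fixed@voxels)
  mrange <- range(moving@voxels)
  center <- as.vector(indexToPhysical(fgeom, (fgeom$dim - 1) / 2))

  affine_models <- intersect(models, c("rigid", "similarity"))
  want_bspline <- "bspline" %in% models
  stages <- list()

  # sampling mask: focus region dilated so boundaries stay visible
  sampleMask <- focusMask
  if (!is.null(sampleMask) && control$sampleDilate > 0) {
    sv <- .dilate(sampleMask@voxels, control$sampleDilate)
    sampleMask <- BinaryMask(sv, spacing = sampleMask@spacing,
                             origin = sampleMask@origin,
                             direction = sampleMask@direction)
  }

  # ---- affine part ----
  p <- c(0, 0, 0, 0, 0, 0) # rx ry rz tx ty tz (+ log-scale for similarity)
  if (control$initCenterOfMass)
    p[4:6] <- .center_of_mass(moving) - .center_of_mass(fixed)
  if (length(affine_models)) {
    model <- if ("similarity" %in% affine_models) "similarity" else "rigid"
    for (lev in seq_len(control$levels)) {
      flev <- fpyr[[lev]]; mlev <- mpyr[[lev]]
      maskArr <- .mask_on_level(sampleMask, geometry(flev))
      smp <- .draw_samples(flev, control$samples, maskArr)
      objective <- function(par, mdl) {
        at <- .affine_from_params(if (mdl == "rigid") c(par, 0) else par,
                                  center, mdl)
        .metric_affine_eval(mlev, smp, at$A, at$t, control$metric,
                            control$mattesBins, frange, mrange)
      }
      nm <- function(par, mdl, scales) {
        stats::optim(par, objective, mdl = mdl, method = "Nelder-Mead",
                     control = list(maxit = control$maxIterations,
                                    parscale = scales, reltol = 1e-9))
      }
      # rigid pass (always), restarted once since Nelder-Mead can stall
      sc6 <- c(0.02, 0.02, 0.02, 2, 2, 2)
      opt <- nm(p[1:6], "rigid", sc6)
      opt <- nm(opt$par, "rigid", sc6)
      p[1:6] <- opt$par
      if (model == "similarity") {
        # multi-start over the log-scale: the discretized-boundary metric
        # has shallow local minima in the scale direction
        p7 <- if (length(p) >= 7) p[7] else 0
        sc7 <- c(sc6, 0.02)
        best <- NULL
        for (ds in c(-0.08, 0, 0.08)) {
          cand <- nm(c(p[1:6], p7 + ds), "similarity", sc7)
          if (is.null(best) || cand$value < best$value) best <- cand
        }
        best <- nm(best$par, "similarity", sc7)
        p <- best$par
      }
    }
    at <- .affine_from_params(if (model == "rigid") c(p[1:6], 0) else p,
                              center, model)
    stages <- c(stages, list(.affine_stage(at$A, at$t)))
  } else if (control$initCenterOfMass && any(p[4:6] != 0) && want_bspline) {
    # no affine model requested: keep identity, do not silently translate
    p[4:6] <- 0
  }

  # ---- deformable part ----
  if (want_bspline) {
    affine_chain <- .new_chain(stages %||%
                                 list(.affine_stage(diag(3), c(0, 0, 0))),
                               fgeom, models = "affine")
    if (!length(stages))
      affine_chain <- identityChain(fgeom)
    # physical bounding box of the fixed domain (RAI: axis-aligned)
    corners <- as.matrix(expand.grid(c(0, fgeom$dim[1] - 1),
                                     c(0, fgeom$dim[2] - 1),
                                     c(0, fgeom$dim[3] - 1)))
    pc <- indexToPhysical(fgeom, corners)
    lo <- apply(pc, 2, min); hi <- apply(pc, 2, max)
    gsp <- rep(control$bsplineSpacing, 3)
    ncp <- pmax(4L, as.integer(ceiling((hi - lo) / gsp)) + 4L)
    gorg <- lo - 1.5 * gsp # pad so every domain point has full support
    coef <- numeric(prod(ncp) * 3)
    defo_levels <- seq(max(1L, control$levels - length(
      control$bsplineIterations) + 1L), control$levels)
    li <- 1L
    focus <- cartilageFocus
    if (!is.null(focus)) {
      fv <- .dilate(focus@voxels, control$focusDilate)
      focus <- BinaryMask(fv, spacing = focus@spacing,
                          origin = focus@origin,
                          direction = focus@direction)
    } else if (!is.null(sampleMask)) focus <- sampleMask
    for (lev in defo_levels) {
      iters <- control$bsplineIterations[li]; li <- li + 1L
      if (iters <= 0) next
      flev <- fpyr[[lev]]
      glev <- geometry(flev)
      # moving pyramid level (same smoothing as the fixed level) resampled
      # through the affine stage onto this level's grid
      mov1 <- resampleImage(mpyr[[lev]], affine_chain, glev,
                            interp = "linear")
      maskArr <- .mask_on_level(focus, glev)
      smp <- .draw_samples(flev, control$samples, maskArr)
      gfloor <- 1e-10 * diff(range(flev@voxels))^2 / min(glev$spacing)
      coef <- cpp_bspline_fit(as.double(mov1@voxels), as.integer(glev$dim),
                              as.double(glev$spacing), as.double(glev$origin),
                              as.double(glev$direction), smp$vals, smp$pts,
                              gorg, gsp, ncp, coef, as.integer(iters),
                              control$bsplineStep, gfloor)
    }
    stages <- c(stages, list(.bspline_stage(gorg, gsp, ncp, coef)))
  }

  chain <- .new_chain(stages, fgeom, models = models)

  # ---- identity-vs-final check on finest-level samples ----
  smp <- .draw_samples(fpyr[[control$levels]], control$samples,
                       .mask_on_level(sampleMask, fgeom))
  mv_id <- .sample_image(moving, smp$pts, "linear", outside = NA_real_)
  mv_fin <- .sample_image(moving, applyTransform(chain, smp$pts), "linear",
                          outside = NA_real_)
  ok_id <- is.finite(mv_id); ok_fin <- is.finite(mv_fin)
  m_id <- if (sum(ok_id) >= 10)
    .paired_metric(smp$vals[ok_id], mv_id[ok_id], control$metric,
                   control$mattesBins) else NA_real_
  m_fin <- if (sum(ok_fin) >= 10)
    .paired_metric(smp$vals[ok_fin], mv_fin[ok_fin], control$metric,
                   control$mattesBins) else Inf
  chain@metric <- c(identity = m_id, final = m_fin)
  # slack so interpolation effects never flag a near-identity solution; the
  # absolute floor is metric-specific (msd is in squared intensity units)
  eps_abs <- switch(control$metric,
                    msd = 1e-4 * diff(frange)^2, ncc = 1e-3, mi = 1e-2)
  if (is.finite(m_id) && !is.na(m_fin) &&
      m_fin - m_id > max(0.05 * abs(m_id), eps_abs)) {
    chain@failed <- TRUE
    warning("registration optimizer ended worse than the identity ",
            "transform; chain flagged as failed")
  }
  chain
}
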