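# Deterministic synthetic phantoms: a half-cylindrical "femur" carrying a
# curved cartilage shell of exactly known wall thickness, mono-exponential
# decay series, and DESS echo pairs. Masks are generated analytically before
# noise/bias are applied, so they are exact; analytic truths are returned
# with the data and never re-derived by tests.

#' Phantom specification
#'
#' The geometry places the cylinder axis along x (the sagittal-stack axis of
#' the canonical frame); the cartilage shell covers the angular span
#' measured from the +y axis in the (y, z) plane.
#'
#' @param dim grid size (nx, ny, nz).
#' @param spacing voxel size in mm.
#' @param boneRadius femur (bone) cylinder radius in mm.
#' @param wall cartilage shell thickness in mm (> 0 and at least one in-plane
#'   voxel).
#' @param span angular span of bone and shell in radians, in (0, 2*pi];
#'   default pi (half cylinder).
#' @param shellLength axial extent of bone and shell in mm (centered in the
#'   grid); default 70% of the grid's axial extent, so the phantom has free
#'   ends and every rigid displacement component is observable.
#' @param levels named intensity levels (background, bone, cartilage).
#' @param noiseSigma Gaussian noise SD in intensity units (Rician noise is
#'   available via `rician = TRUE`).
#' @param biasAmplitude relative amplitude of a smooth multiplicative gain
#'   field (0 disables).
#' @param shift rigid displacement (mm, length 3) of the phantom inside the
#'   grid; applied analytically so masks remain exact.
#' @param rotation rotation about the cylinder axis in radians, applied like
#'   `shift`.
#' @param rician use Rician (magnitude) instead of additive Gaussian noise.
#' @param seed RNG seed fixing all randomness.
#' @return A validated list of class "PhantomSpec".
#' @export
phantomSpec <- function(dim = c(24L, 120L, 120L), spacing = c(1, 0.5, 0.5),
                        boneRadius = 20, wall = 2, span = pi,
                        shellLength = NULL,
                        levels = c(background = 5, bone = 40,
                                   cartilage = 90),
                        noiseSigma = 0, biasAmplitude = 0,
                        shift = c(0, 0, 0), rotation = 0, rician = FALSE,
                        seed = 1L) {
  stopifnot(length(dim) == 3L, all(dim >= 2), length(spacing) == 3L,
            all(spacing > 0), boneRadius > 0, wall > 0, span > 0,
            span <= 2 * pi + 1e-12, noiseSigma >= 0, biasAmplitude >= 0,
            length(shift) == 3L)
  if (wall < max(spacing[2:3]))
    stop("cartilage wall (", wall, " mm) is thinner than one in-plane voxel")
  if (is.null(shellLength)) shellLength <- 0.7 * dim[1] * spacing[1]
  stopifnot(shellLength > 0)
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 boneRadius = boneRadius, wall = wall, span = span,
                 shellLength = shellLength,
                 levels = levels, noiseSigma = noiseSigma,
                 biasAmplitude = biasAmplitude, shift = as.numeric(shift),
                 rotation = rotation, rician = isTRUE(rician),
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' Generate a knee phantom (image + masks + analytic truth)
#'
#' Builds a half-cylindrical bone with an attached cartilage shell of
#' exactly the requested wall thickness. Noise, bias and rigid displacement
#' are applied to the intensity image only (displacement analytically, by
#' evaluating the model at displaced coordinates), so the returned masks are
#' the exact voxelization of the displaced analytic shapes.
#'
#' @param spec a [phantomSpec()] list.
#' @return list with `image` ([Image3D-class]), `femurMask`,
#'   `cartilageMask` ([BinaryMask-class]) and `truth` (wall mm, analytic
#'   shell volume mm^3, bone radius mm, shell length mm).
#' @export
makeKneePhantom <- function(spec = phantomSpec()) {
  stopifnot(inherits(spec, "PhantomSpec"))
  d <- spec$dim; sp <- spec$spacing
  # physical voxel-center coordinates (origin 0, identity direction)
  px <- (seq_len(d[1]) - 1) * sp[1]
  py <- (seq_len(d[2]) - 1) * sp[2]
  pz <- (seq_len(d[3]) - 1) * sp[3]
  # in-plane phantom center: centered in y, low in z so the span fits
  ctr <- c(mean(range(py)), 0.25 * max(pz)) + spec$shift[2:3]
  dy <- rep(py, times = d[3]) - ctr[1]
  dz <- rep(pz, each = d[2]) - ctr[2]
  if (spec$rotation != 0) {
    cr <- cos(-spec$rotation); sr <- sin(-spec$rotation)
    tmp <- dy * cr - dz * sr
    dz <- dy * sr + dz * cr
    dy <- tmp
  }
  r <- sqrt(dy^2 + dz^2)
  th <- atan2(dz, dy)
  inspan <- th >= 0 & th <= spec$span
  bone2d <- r <= spec$boneRadius & inspan
  cart2d <- r > spec$boneRadius & r <= spec$boneRadius + spec$wall & inspan
  femur <- array(0, d); cart <- array(0, d)
  plane_b <- matrix(as.double(bone2d), d[2], d[3])
  plane_c <- matrix(as.double(cart2d), d[2], d[3])
  xmid <- mean(range(px)) + spec$shift[1]
  inax <- abs(px - xmid) <= spec$shellLength / 2
  for (i in which(inax)) {
    femur[i, , ] <- plane_b
    cart[i, , ] <- plane_c
  }
  img <- array(spec$levels[["background"]], d)
  img[femur > 0] <- spec$levels[["bone"]]
  img[cart > 0] <- spec$levels[["cartilage"]]
  if (spec$biasAmplitude > 0) {
    gy <- 1 + spec$biasAmplitude * (2 * (py - min(py)) / diff(range(py)) - 1)
    gz <- 1 + 0.5 * spec$biasAmplitude *
      (2 * (pz - min(pz)) / diff(range(pz)) - 1)
    gain <- rep(1, d[1]) %o% gy %o% gz
    img <- img * gain
  }
  if (spec$noiseSigma > 0) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(spec$seed)
    if (spec$rician) {
      n1 <- array(stats::rnorm(prod(d), 0, spec$noiseSigma), d)
      n2 <- array(stats::rnorm(prod(d), 0, spec$noiseSigma), d)
      img <- sqrt((img + n1)^2 + n2^2)
    } else {
      img <- img + array(stats::rnorm(prod(d), 0, spec$noiseSigma), d)
    }
  }
  img[img < 0] <- 0
  # axial extent covered by voxel centers (each center represents one
  # spacing of axial length)
  shell_len <- sum(inax) * sp[1]
  truth <- list(wall = spec$wall,
                volume = spec$span / 2 *
                  ((spec$boneRadius + spec$wall)^2 - spec$boneRadius^2) *
                  shell_len,
                boneRadius = spec$boneRadius, shellLength = shell_len)
  geom <- list(spacing = sp, origin = c(0, 0, 0), direction = diag(3))
  list(image = Image3D(img, sp, geom$origin, geom$direction,
                       modality = "phantom"),
       femurMask = BinaryMask(femur, sp, geom$origin, geom$direction),
       cartilageMask = BinaryMask(cart, sp, geom$origin, geom$direction),
       truth = truth)
}

#' The five-phantom fixture cohort
#'
#' Bone radii 18-22 mm with walls 1.6-2.4 mm; the middle phantom (radius
#' 20 mm, wall 2.0 mm) is the cohort's mean shape. Each phantom carries a
#' small deterministic rigid displacement and mild Gaussian noise so the
#' cohort exercises both the rigid and the deformable registration stages.
#'
#' @param dim,spacing grid geometry shared by the cohort.
#' @param noiseSigma per-phantom Gaussian noise SD (intensity units).
#' @param seed base RNG seed; phantom i uses seed + i.
#' @return list of 5 phantom lists (as from [makeKneePhantom()]) with a
#'   `truth` data.frame attribute.
#' @export
makePhantomCohort <- function(dim = c(24L, 120L, 120L),
                              spacing = c(1, 0.5, 0.5), noiseSigma = 2,
                              seed = 1L) {
  radii <- 18:22
  walls <- seq(1.6, 2.4, by = 0.2)
  shifts <- outer(-2:2, c(0.8, -0.6, 0.4)) # mm, deterministic per phantom
  # shell length scales with the radius so the phantoms differ by a
  # (roughly) isotropic scaling about the mean shape
  cohort <- lapply(1:5, function(i)
    makeKneePhantom(phantomSpec(dim = dim, spacing = spacing,
                                boneRadius = radii[i], wall = walls[i],
                                shellLength = 0.84 * radii[i],
                                shift = shifts[i, ],
                                noiseSigma = noiseSigma,
                                seed = seed + i)))
  attr(cohort, "truth") <- data.frame(
    phantom = 1:5, bone_radius_mm = radii, wall_mm = walls,
    volume_mm3 = vapply(cohort, function(p) p$truth$volume, numeric(1)))
  cohort
}

#' Generate a mono-exponential decay series with known truth
#'
#' Volumes follow S(Ta) = K exp(-Ta/Tb) voxelwise, plus optional Gaussian
#' noise. `tb`/`k` may be scalars or arrays on the geometry.
#'
#' @param tb relaxation time(s) in ms (positive).
#' @param k signal amplitude(s).
#' @param times acquisition times in ms, strictly increasing (default the
#'   spin-lock grid 1, 10, 30, 60).
#' @param sigma Gaussian noise SD.
#' @param seed RNG seed.
#' @param geom geometry list (dim, spacing, origin, direction); default a
#'   10 x 10 x 2 grid of 0.5 mm in-plane voxels.
#' @param kind "T1rho" or "T2w".
#' @return list with `series` ([DecaySeries-class]) and `truth` (tb and k
#'   arrays).
#' @export
makeDecaySeries <- function(tb = 40, k = 100, times = c(1, 10, 30, 60),
                            sigma = 0, seed = 1L, geom = NULL,
                            kind = "T1rho") {
  if (any(tb <= 0)) stop("tb must be positive")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(geom))
    geom <- list(dim = c(10L, 10L, 2L), spacing = c(0.5, 0.5, 3),
                 origin = c(0, 0, 0), direction = diag(3))
  d <- geom$dim
  tbArr <- array(tb, d); kArr <- array(k, d)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  vols <- lapply(times, function(t) {
    s <- kArr * exp(-t / tbArr)
    if (sigma > 0) s <- s + array(stats::rnorm(prod(d), 0, sigma), d)
    Image3D(s, geom$spacing, geom$origin, geom$direction)
  })
  list(series = decaySeries(vols, times, kind),
       truth = list(tb = tbArr, k = kArr))
}

#' Generate a DESS echo pair with known T2
#'
#' Echoes follow the same forward model that [t2FromDess()] inverts:
#' S1 = `s1Level`, S2 = S1 * [dessRatio()], plus optional Gaussian noise.
#'
#' @param t2 true T2 in ms (scalar or array on the geometry).
#' @param params a [dessParams()] list.
#' @param sigma Gaussian noise SD.
#' @param seed RNG seed.
#' @param geom geometry list; default as in [makeDecaySeries()].
#' @param s1Level first-echo amplitude.
#' @return list with `echo1`, `echo2` ([Image3D-class]) and `truth` (t2
#'   array).
#' @export
makeDessPair <- function(t2 = 40, params = dessParams(16.32, 4.7, 25),
                         sigma = 0, seed = 1L, geom = NULL, s1Level = 100) {
  stopifnot(inherits(params, "DessParams"))
  if (any(t2 <= 0)) stop("t2 outside the model's valid domain")
  if (is.null(geom))
    geom <- list(dim = c(10L, 10L, 2L), spacing = c(0.5, 0.5, 3),
                 origin = c(0, 0, 0), direction = diag(3))
  d <- geom$dim
  t2Arr <- array(t2, d)
  s1 <- array(s1Level, d)
  s2 <- s1 * dessRatio(as.vector(t2Arr), params)
  s2 <- array(s2, d)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  if (sigma > 0) {
    s1 <- s1 + array(stats::rnorm(prod(d), 0, sigma), d)
    s2 <- s2 + array(stats::rnorm(prod(d), 0, sigma), d)
  }
  list(echo1 = Image3D(s1, geom$spacing, geom$origin, geom$direction),
       echo2 = Image3D(s2, geom$spacing, geom$origin, geom$direction),
       truth = list(t2 = t2Arr))
}
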