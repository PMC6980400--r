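# Transform chains: construction, application, rendering, inversion,
# resampling and mask warping.
#
# Mapping convention: a chain maps points of the FIXED image domain into the
# MOVING image domain (the resampling convention). Stages are stored in fit
# order (coarse -> fine); application composes with the finest stage applied
# to the point first, matching how stages are estimated on progressively
# resampled images.

.affine_stage <- function(A, t) {
  list(type = 1L, A = as.double(A), t = as.double(t))
}

.bspline_stage <- function(grid_origin, grid_spacing, grid_dim, coef) {
  list(type = 2L, grid_origin = as.double(grid_origin),
       grid_spacing = as.double(grid_spacing),
       grid_dim = as.integer(grid_dim), coef = as.double(coef))
}

.field_stage <- function(field, geom) {
  list(type = 3L, field = as.double(field), dim = as.integer(geom$dim),
       spacing = as.double(geom$spacing), origin = as.double(geom$origin),
       direction = as.double(geom$direction))
}

.new_chain <- function(stages, fixedGeometry, models, failed = FALSE,
                       metric = c(identity = NA_real_, final = NA_real_)) {
  new("TransformChain", stages = stages, fixedGeometry = fixedGeometry,
      models = models, failed = failed, metric = metric)
}

#' Identity transform chain
#'
#' @param geom geometry list or image defining the fixed domain.
#' @return A [TransformChain-class] that maps every point to itself.
#' @export
identityChain <- function(geom) {
  .new_chain(list(.affine_stage(diag(3), c(0, 0, 0))), .as_geom(geom),
             models = "identity")
}

#' Apply a transform chain to points
#'
#' @param chain a [TransformChain-class].
#' @param points n x 3 matrix (or length-3 vector) of physical coordinates in
#'   the fixed domain.
#' @return n x 3 matrix of mapped coordinates in the moving domain.
#' @export
applyTransform <- function(chain, points) {
  stopifnot(is(chain, "TransformChain"))
  cpp_transform_points(.as_points(points), chain@stages)
}

#' Render a chain as a dense displacement field
#'
#' Evaluates u(x) = T(x) - x at every voxel center of `geom`.
#'
#' @param chain a [TransformChain-class].
#' @param geom target geometry (default: the chain's fixed geometry).
#' @return A [DisplacementField-class] in mm.
#' @export
renderField <- function(chain, geom = NULL) {
  stopifnot(is(chain, "TransformChain"))
  g <- .as_geom(geom %||% chain@fixedGeometry)
  f <- cpp_render_field(chain@stages, as.integer(g$dim),
                        as.double(g$spacing), as.double(g$origin),
                        as.double(g$direction))
  new("DisplacementField", field = array(f, c(g$dim, 3)),
      spacing = g$spacing, origin = g$origin, direction = g$direction)
}

#' Construct a DisplacementField
#'
#' @param field 4D array (nx, ny, nz, 3) of displacements in mm.
#' @param spacing,origin,direction grid geometry.
#' @return A [DisplacementField-class].
#' @export
displacementField <- function(field, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0), direction = diag(3)) {
  new("DisplacementField", field = field, spacing = as.numeric(spacing),
      origin = as.numeric(origin), direction = direction)
}

# compose all-affine stages of a chain into a single (A, t):
# T(x) = s1(s2(...sn(x)))
.compose_affine <- function(stages) {
  A <- diag(3); t <- c(0, 0, 0)
  for (st in rev(stages)) { # apply order: last stage first
    As <- matrix(st$A, 3, 3); ts <- st$t
    A <- As %*% A
    t <- as.vector(As %*% t) + ts
  }
  list(A = A, t = t)
}

.all_affine <- function(chain) {
  all(vapply(chain@stages, function(s) s$type == 1L, logical(1)))
}

#' Invert a transform chain
#'
#' Chains made only of rigid/similarity (affine) stages are inverted in
#' closed form. Chains containing B-spline or dense-field stages are rendered
#' to a displacement field and inverted by fixed-point iteration (at most
#' `maxit` iterations, tolerance `0.1 * min(spacing)`); non-invertible
#' (folding) regions trigger a warning reporting the worst residual.
#'
#' @param chain a [TransformChain-class].
#' @param geom geometry on which to define the inverse (normally the moving
#'   image geometry); defaults to the chain's fixed geometry.
#' @param maxit maximum fixed-point iterations per voxel.
#' @return A [TransformChain-class] mapping moving-domain points back to the
#'   fixed domain.
#' @export
invertTransform <- function(chain, geom = NULL, maxit = 50L) {
  stopifnot(is(chain, "TransformChain"))
  if (.all_affine(chain)) {
    comp <- .compose_affine(chain@stages)
    Ai <- solve(comp$A)
    ti <- -as.vector(Ai %*% comp$t)
    return(.new_chain(list(.affine_stage(Ai, ti)),
                      .as_geom(geom %||% chain@fixedGeometry),
                      models = paste0("inverse-", chain@models)))
  }
  fg <- .as_geom(chain@fixedGeometry)
  # decompose T = Aff o Rest (leading affine stages are applied last): then
  # T^{-1} = Rest^{-1} o Aff^{-1}, with only the (small, well-conditioned)
  # deformable remainder inverted numerically on the fixed geometry
  types <- vapply(chain@stages, function(s) s$type, integer(1))
  naff <- if (any(types != 1L)) min(which(types != 1L)) - 1L
          else length(types)
  inv_stages <- list()
  if (naff > 0L) {
    comp <- .compose_affine(chain@stages[seq_len(naff)])
    Ai <- solve(comp$A)
    inv_stages <- list(.affine_stage(Ai, -as.vector(Ai %*% comp$t)))
  }
  rest <- chain@stages[seq.int(naff + 1L, length(types))]
  rest_chain <- .new_chain(rest, fg, models = "rest")
  fwd <- renderField(rest_chain, fg)
  tol <- 0.1 * min(fg$spacing)
  res <- cpp_invert_field(as.double(fwd@field), as.integer(fg$dim),
                          as.double(fg$spacing), as.double(fg$origin),
                          as.double(fg$direction), as.integer(fg$dim),
                          as.double(fg$spacing), as.double(fg$origin),
                          as.double(fg$direction), as.integer(maxit), tol)
  if (res$mean_residual > tol)
    warning(sprintf(paste0("displacement-field inversion did not converge ",
                           "(mean residual %.3g mm, worst %.3g mm); the ",
                           "field may fold (negative Jacobian region)"),
                    res$mean_residual, res$worst_residual))
  inv <- .new_chain(c(list(.field_stage(array(res$field, c(fg$dim, 3)),
                                        fg)), inv_stages),
                    .as_geom(geom %||% fg),
                    models = paste0("inverse-", chain@models))
  inv@metric <- c(identity = NA_real_, final = res$worst_residual)
  inv
}

#' Resample an image through a transform chain
#'
#' For every voxel center y of `targetGeom`, samples the moving image at
#' T(y).
#'
#' @param image the moving [Image3D-class].
#' @param chain a [TransformChain-class] mapping target-domain points into
#'   the image's domain.
#' @param targetGeom output geometry (default: the chain's fixed geometry).
#' @param interp "linear" or "nearest".
#' @param outside fill value outside the moving image.
#' @return An [Image3D-class] on `targetGeom`.
#' @export
resampleImage <- function(image, chain, targetGeom = NULL,
                          interp = c("linear", "nearest"), outside = 0) {
  stopifnot(is(image, "Image3D"), is(chain, "TransformChain"))
  interp <- match.arg(interp)
  mg <- geometry(image)
  tg <- .as_geom(targetGeom %||% chain@fixedGeometry)
  vox <- cpp_resample(as.double(image@voxels), as.integer(mg$dim),
                      as.double(mg$spacing), as.double(mg$origin),
                      as.double(mg$direction), as.integer(tg$dim),
                      as.double(tg$spacing), as.double(tg$origin),
                      as.double(tg$direction), chain@stages,
                      if (interp == "linear") 1L else 0L, outside)
  Image3D(array(vox, tg$dim), spacing = tg$spacing, origin = tg$origin,
          direction = tg$direction, modality = image@modality)
}

#' Warp a binary mask through a transform chain
#'
#' Nearest-neighbour resampling so the label set \{0, 1\} is closed under
#' warping. The chain must map target-domain points into the mask's domain
#' (for atlas propagation this is the INVERTED registration chain).
#'
#' @param mask a [BinaryMask-class].
#' @param chain a [TransformChain-class].
#' @param targetGeom output geometry.
#' @return A [BinaryMask-class] on `targetGeom`.
#' @export
warpMask <- function(mask, chain, targetGeom = NULL) {
  stopifnot(is(mask, "BinaryMask"))
  out <- resampleImage(mask, chain, targetGeom, interp = "nearest",
                       outside = 0)
  BinaryMask(out@voxels, spacing = out@spacing, origin = out@origin,
             direction = out@direction)
}

#' Average displacement fields
#'
#' Voxelwise arithmetic mean of fields sharing one geometry. The result is
#' meaningful (and compared) only inside `region`.
#'
#' @param fields nonempty list of [DisplacementField-class] on one geometry.
#' @param region a [BinaryMask-class] on the same geometry.
#' @return A [DisplacementField-class].
#' @export
averageFields <- function(fields, region = NULL) {
  if (!length(fields)) stop("cannot average an empty list of fields")
  g0 <- geometry(fields[[1]])
  for (f in fields)
    if (!sameGeometry(geometry(f), g0)) .stop_geometry_mismatch("fields")
  if (!is.null(region) && !sameGeometry(geometry(region), g0))
    .stop_geometry_mismatch("fields and region")
  acc <- fields[[1]]@field
  if (length(fields) > 1L)
    for (i in 2:length(fields)) acc <- acc + fields[[i]]@field
  new("DisplacementField", field = acc / length(fields),
      spacing = g0$spacing, origin = g0$origin, direction = g0$direction)
}

#' Mean Euclidean distance between two displacement fields
#'
#' Mean over the region's voxels of ||f - g||_2 (mm). A metric on fields
#' restricted to the region: nonnegative, symmetric, zero iff the fields
#' agree there.
#'
#' @param f,g [DisplacementField-class] on one geometry.
#' @param region nonempty [BinaryMask-class] on the same geometry.
#' @return Mean distance in mm.
#' @export
fieldDistance <- function(f, g, region) {
  if (!sameGeometry(geometry(f), geometry(g)) ||
      !sameGeometry(geometry(f), geometry(region)))
    .stop_geometry_mismatch("fields and region")
  sel <- region@voxels > 0
  if (!any(sel)) stop("field comparison region is empty")
  d <- f@field - g@field
  nrm <- sqrt(d[, , , 1][sel]^2 + d[, , , 2][sel]^2 + d[, , , 3][sel]^2)
  mean(nrm)
}

# binary dilation by r steps of the 6-neighbourhood (L1 ball radius r)
.dilate <- function(arr, r = 3L) {
  d <- dim(arr)
  out <- arr > 0
  for (it in seq_len(r)) {
    nb <- out
    nb[-1, , ] <- nb[-1, , ] | out[-d[1], , ]
    nb[-d[1], , ] <- nb[-d[1], , ] | out[-1, , ]
    nb[, -1, ] <- nb[, -1, ] | out[, -d[2], ]
    nb[, -d[2], ] <- nb[, -d[2], ] | out[, -1, ]
    nb[, , -1] <- nb[, , -1] | out[, , -d[3]]
    nb[, , -d[3]] <- nb[, , -d[3]] | out[, , -1]
    out <- nb
  }
  array(as.double(out), d)
}
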