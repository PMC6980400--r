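#' @import methods
NULL

#' Image3D: a 3D scalar image with physical geometry
#'
#' The basic image container of the workflow. Voxels are stored in a
#' column-major array with the first (x) index fastest. Indexing is 0-based in
#' all geometry computations: the physical position of voxel index
#' \eqn{i = (i_x, i_y, i_z)} is \eqn{origin + D (spacing \odot i)} where the
#' columns of the orthonormal direction matrix \eqn{D} are the axis
#' directions. The canonical anatomical frame after spatial standardization is
#' RAI storage order with +x toward the patient's left, +y posterior and
#' +z superior, and identity direction matrix.
#'
#' @slot voxels 3D numeric array of intensities.
#' @slot spacing voxel size in mm along each axis (strictly positive).
#' @slot origin physical position (mm) of voxel (0,0,0).
#' @slot direction 3x3 orthonormal matrix; column j is the physical direction
#'   of image axis j.
#' @slot modality free-text modality tag (e.g. "DESS", "T2w").
#' @export
setClass("Image3D",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 direction = "matrix", modality = "character"),
  prototype(voxels = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0), direction = diag(3), modality = ""))

.orthonormal <- function(m, tol = 1e-6) {
  is.matrix(m) && all(dim(m) == c(3, 3)) && all(is.finite(m)) &&
    max(abs(crossprod(m) - diag(3))) < tol
}

setValidity("Image3D", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L) return("voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be three strictly positive values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be three finite values")
  if (!.orthonormal(object@direction))
    return("direction must be a 3x3 orthonormal matrix (tolerance 1e-6)")
  TRUE
})

#' BinaryMask: an Image3D restricted to labels {0, 1}
#'
#' Shares the full geometry model of [Image3D-class]; voxel values are 0
#' (background) or 1 (foreground). All resampling operations on masks in this
#' package use nearest-neighbour interpolation so the label set is closed.
#'
#' @export
setClass("BinaryMask", contains = "Image3D")

setValidity("BinaryMask", function(object) {
  u <- unique(as.vector(object@voxels))
  if (!all(u %in% c(0, 1))) return("mask voxels must be exactly 0 or 1")
  TRUE
})

#' Construct an Image3D
#'
#' @param voxels 3D numeric array.
#' @param spacing,origin numeric length-3 (mm).
#' @param direction 3x3 orthonormal matrix, columns = axis directions.
#' @param modality free-text tag.
#' @return An [Image3D-class] object.
#' @examples
#' img <- Image3D(array(rnorm(60), c(3, 4, 5)), spacing = c(0.5, 0.5, 1))
#' dim(img)
#' @export
Image3D <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                    direction = diag(3), modality = "") {
  new("Image3D", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), direction = direction, modality = modality)
}

#' Construct a BinaryMask
#'
#' @param voxels 3D array with values in \{0, 1\}.
#' @inheritParams Image3D
#' @return A [BinaryMask-class] object.
#' @export
BinaryMask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       direction = diag(3), modality = "") {
  storage.mode(voxels) <- "double"
  new("BinaryMask", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), direction = direction, modality = modality)
}

#' ImageList: records of images (and masks) to process
#'
#' Parsed from a plain-text list file (see [parseImageList()]) or built
#' programmatically. One row per image with optional femur / cartilage mask
#' paths, laterality and role.
#'
#' @slot records data.frame with columns image_path, femur_mask_path,
#'   cartilage_mask_path (NA when absent), laterality ("left"/"right"),
#'   role ("reference"/"moving"/"ground_truth").
#' @export
setClass("ImageList", representation(records = "data.frame"))

setValidity("ImageList", function(object) {
  need <- c("image_path", "femur_mask_path", "cartilage_mask_path",
            "laterality", "role")
  if (!all(need %in% names(object@records)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  lat <- object@records$laterality
  if (length(lat) && !all(lat %in% c("left", "right")))
    return("laterality must be 'left' or 'right'")
  role <- object@records$role
  if (length(role) && !all(role %in% c("reference", "moving", "ground_truth")))
    return("role must be one of reference/moving/ground_truth")
  TRUE
})

#' TransformChain: an ordered sequence of spatial transform stages
#'
#' A chain maps points of the fixed image domain into the moving image domain
#' (the resampling convention). Stages are stored in fit order, coarse to
#' fine; the composite applies the finest stage to a point first. Stage models
#' are "rigid", "similarity" (stored as one affine stage), "bspline"
#' (cubic B-spline displacement on a control grid) and "field" (dense
#' displacement field, e.g. a numerically inverted chain).
#'
#' @slot stages list of stage descriptors (internal layout, see
#'   [applyTransform()]).
#' @slot fixedGeometry geometry list (dim, spacing, origin, direction) of the
#'   fixed image the chain was estimated on.
#' @slot models character vector of the registration models that produced the
#'   chain, in application order (e.g. c("rigid", "similarity", "bspline")).
#' @slot failed TRUE when the optimizer ended worse than the identity
#'   transform; the chain is still usable but flagged.
#' @slot metric named numeric: similarity metric at identity and at the
#'   optimum, for the run log.
#' @export
setClass("TransformChain",
  representation(stages = "list", fixedGeometry = "list",
                 models = "character", failed = "logical",
                 metric = "numeric"),
  prototype(stages = list(), fixedGeometry = list(), models = character(),
            failed = FALSE, metric = c(identity = NA_real_, final = NA_real_)))

#' DisplacementField: a dense 3-vector field on an image grid
#'
#' Displacements are in mm, stored as a 4D array (nx, ny, nz, 3) on a stated
#' geometry. A zero field composed with any image is the identity resampling.
#'
#' @slot field 4D numeric array (nx, ny, nz, 3).
#' @slot spacing,origin,direction grid geometry as in [Image3D-class].
#' @export
setClass("DisplacementField",
  representation(field = "array", spacing = "numeric", origin = "numeric",
                 direction = "matrix"))

setValidity("DisplacementField", function(object) {
  d <- dim(object@field)
  if (length(d) != 4L || d[4] != 3L)
    return("field must be a 4D array with 3 components")
  if (any(!is.finite(object@field))) return("field must be finite everywhere")
  TRUE
})

#' DecaySeries: co-registered volumes along a relaxation decay
#'
#' Ordered image volumes with strictly increasing acquisition times (echo
#' time TE for T2-weighted data, spin-lock time TSL for T1rho-weighted data),
#' all sharing one geometry.
#'
#' @slot volumes list of [Image3D-class], identical geometry.
#' @slot times acquisition times in ms, strictly increasing.
#' @slot kind "T2w" or "T1rho".
#' @export
setClass("DecaySeries",
  representation(volumes = "list", times = "numeric", kind = "character"))

setValidity("DecaySeries", function(object) {
  if (length(object@volumes) < 2L) return("a decay series needs >= 2 volumes")
  if (length(object@times) != length(object@volumes))
    return("one acquisition time per volume")
  if (any(diff(object@times) <= 0))
    return("acquisition times must be strictly increasing")
  if (!object@kind %in% c("T2w", "T1rho"))
    return("kind must be 'T2w' or 'T1rho'")
  g0 <- geometry(object@volumes[[1]])
  for (v in object@volumes)
    if (!sameGeometry(geometry(v), g0))
      return("all volumes must share one geometry")
  TRUE
})

#' FitResult: voxelwise relaxometry fit maps
#'
#' @slot tbMap [Image3D-class] of relaxation times (ms); invalid voxels carry
#'   NA and are excluded from statistics.
#' @slot kMap [Image3D-class] of the signal amplitude K; NA where invalid.
#' @slot validMask [BinaryMask-class], 1 where the fit succeeded.
#' @slot method "exponential", "linear" or "dess".
#' @export
setClass("FitResult",
  representation(tbMap = "Image3D", kMap = "Image3D",
                 validMask = "BinaryMask", method = "character"))

#' CartilageSurfaces: split cartilage surfaces with flattening and thickness
#'
#' Point clouds in physical mm. Each subchondral point carries exactly one
#' flattened 2D coordinate (arc length along the fitted cylinder, slice
#' position) and one thickness value.
#'
#' @slot subchondral n x 3 matrix (mm), bone-facing surface points.
#' @slot articular m x 3 matrix (mm), joint-facing surface points.
#' @slot flatCoords n x 2 matrix: (theta * r_mean, slice position) in mm.
#' @slot thickness length-n vector (mm), nearest-neighbour 3D distances.
#' @slot sliceAxis the medial-lateral (sagittal stack) axis index (1-3).
#' @export
setClass("CartilageSurfaces",
  representation(subchondral = "matrix", articular = "matrix",
                 flatCoords = "matrix", thickness = "numeric",
                 sliceAxis = "numeric"))

setValidity("CartilageSurfaces", function(object) {
  n <- nrow(object@subchondral)
  if (nrow(object@flatCoords) != n || length(object@thickness) != n)
    return("every subchondral point needs one flat coordinate and thickness")
  if (length(object@thickness) && any(object@thickness < 0, na.rm = TRUE))
    return("thickness must be nonnegative")
  if (length(object@flatCoords) && any(!is.finite(object@flatCoords)))
    return("flat coordinates must be finite")
  TRUE
})
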