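# index <-> physical mapping and geometry utilities.
# Indices are 0-based; arrays are x-fastest.

#' Map 0-based voxel indices to physical coordinates
#'
#' Physical position of index i is origin + direction %*% (spacing * i).
#' Continuous (fractional) indices are allowed.
#'
#' @param geom geometry list (dim, spacing, origin, direction) as returned by
#'   [geometry()], or an [Image3D-class].
#' @param index n x 3 matrix (or length-3 vector) of 0-based indices.
#' @return n x 3 matrix of physical coordinates (mm).
#' @examples
#' img <- Image3D(array(0, c(4, 4, 4)), spacing = c(2, 2, 2),
#'                origin = c(1, 1, 1))
#' indexToPhysical(img, c(1, 0, 0))  # c(3, 1, 1)
#' @export
indexToPhysical <- function(geom, index) {
  g <- .as_geom(geom)
  idx <- .as_points(index)
  scaled <- sweep(idx, 2, g$spacing, `*`)
  t(g$direction %*% t(scaled) + g$origin)
}

#' Map physical coordinates to 0-based (continuous) voxel indices
#'
#' Inverse of [indexToPhysical()]; exact for orthonormal direction matrices.
#'
#' @inheritParams indexToPhysical
#' @param point n x 3 matrix (or length-3 vector) of physical coordinates.
#' @return n x 3 matrix of continuous 0-based indices.
#' @export
physicalToIndex <- function(geom, point) {
  g <- .as_geom(geom)
  pts <- .as_points(point)
  rel <- t(t(g$direction) %*% (t(pts) - g$origin))
  sweep(rel, 2, g$spacing, `/`)
}

.as_geom <- function(x) {
  if (is(x, "Image3D") || is(x, "DisplacementField")) return(geometry(x))
  stopifnot(is.list(x), all(c("dim", "spacing", "origin", "direction")
                            %in% names(x)))
  x
}

.as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  storage.mode(p) <- "double"
  p
}

#' Compare two geometries
#'
#' @param a,b geometry lists or images.
#' @param tol absolute tolerance on spacing/origin/direction.
#' @return TRUE when dims match exactly and the continuous geometry agrees
#'   within `tol`.
#' @export
sameGeometry <- function(a, b, tol = 1e-6) {
  ga <- .as_geom(a); gb <- .as_geom(b)
  all(ga$dim == gb$dim) &&
    max(abs(ga$spacing - gb$spacing)) < tol &&
    max(abs(ga$origin - gb$origin)) < tol &&
    max(abs(ga$direction - gb$direction)) < tol
}

.stop_geometry_mismatch <- function(what = "inputs") {
  stop(what, " must share the same geometry (dim/spacing/origin/direction)",
       call. = FALSE)
}

# voxel centers of a geometry as an n x 3 physical matrix, optionally only
# where mask (logical/0-1 vector or array) is TRUE
.grid_points <- function(geom, mask = NULL) {
  g <- .as_geom(geom)
  d <- g$dim
  idx <- cbind(
    rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
    rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  if (!is.null(mask)) idx <- idx[as.vector(mask) > 0, , drop = FALSE]
  indexToPhysical(g, idx)
}

# sample an image at physical points
.sample_image <- function(img, pts, interp = c("linear", "nearest"),
                          outside = 0) {
  interp <- match.arg(interp)
  g <- geometry(img)
  cpp_sample_image(as.double(img@voxels), as.integer(g$dim),
                   as.double(g$spacing), as.double(g$origin),
                   as.double(g$direction), .as_points(pts),
                   if (interp == "linear") 1L else 0L, outside)
}
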