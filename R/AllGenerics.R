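#' Accessors for image containers
#'
#' `voxels()` returns the raw 3D array, `spacing()`, `origin()`, `direction()`
#' and `modality()` the geometry/metadata slots, and `geometry()` a compact
#' list (dim, spacing, origin, direction) used throughout the registration
#' layer.
#'
#' @param x an [Image3D-class] (or subclass) object.
#' @param value replacement value.
#' @return The corresponding slot (see Details); `geometry()` returns a list.
#' @name image-accessors
NULL

#' @rdname image-accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname image-accessors
#' @export
setGeneric("voxels<-", function(x, value) standardGeneric("voxels<-"))
#' @rdname image-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname image-accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname image-accessors
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))
#' @rdname image-accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname image-accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname image-accessors
#' @export
setMethod("voxels", "Image3D", function(x) x@voxels)

#' @rdname image-accessors
#' @export
setMethod("voxels<-", "Image3D", function(x, value) {
  x@voxels <- value
  validObject(x)
  x
})

#' @rdname image-accessors
#' @export
setMethod("spacing", "Image3D", function(x) x@spacing)
#' @rdname image-accessors
#' @export
setMethod("origin", "Image3D", function(x) x@origin)
#' @rdname image-accessors
#' @export
setMethod("direction", "Image3D", function(x) x@direction)
#' @rdname image-accessors
#' @export
setMethod("modality", "Image3D", function(x) x@modality)

#' @rdname image-accessors
#' @export
setMethod("geometry", "Image3D", function(x)
  list(dim = dim(x@voxels), spacing = x@spacing, origin = x@origin,
       direction = x@direction))

#' @rdname image-accessors
#' @export
setMethod("geometry", "DisplacementField", function(x)
  list(dim = dim(x@field)[1:3], spacing = x@spacing, origin = x@origin,
       direction = x@direction))

#' @describeIn Image3D dimensions of the voxel grid.
#' @param x an Image3D.
#' @export
setMethod("dim", "Image3D", function(x) dim(x@voxels))

setMethod("show", "Image3D", function(object) {
  d <- dim(object@voxels)
  cat(class(object), sprintf("%d x %d x %d", d[1], d[2], d[3]),
      sprintf("| spacing %s mm", paste(signif(object@spacing, 4),
                                       collapse = " x ")),
      sprintf("| origin (%s)", paste(signif(object@origin, 4),
                                     collapse = ", ")), "\n")
  if (nzchar(object@modality)) cat("  modality:", object@modality, "\n")
  rng <- range(object@voxels)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@voxels)
  cat("BinaryMask", sprintf("%d x %d x %d", d[1], d[2], d[3]),
      sprintf("| spacing %s mm", paste(signif(object@spacing, 4),
                                       collapse = " x ")),
      sprintf("| %d foreground voxels\n", sum(object@voxels)))
})

setMethod("show", "ImageList", function(object) {
  cat("ImageList with", nrow(object@records), "records\n")
  if (nrow(object@records))
    print(utils::head(object@records, 5))
})

setMethod("show", "TransformChain", function(object) {
  cat("TransformChain:", paste(object@models, collapse = " + "),
      if (object@failed) "[FAILED]" else "", "\n")
  cat(sprintf("  metric identity -> final: %.6g -> %.6g\n",
              object@metric[["identity"]], object@metric[["final"]]))
})

setMethod("show", "DecaySeries", function(object) {
  cat("DecaySeries (", object@kind, "): ", length(object@volumes),
      " volumes at times [", paste(object@times, collapse = ", "),
      "] ms\n", sep = "")
})

setMethod("show", "FitResult", function(object) {
  v <- object@tbMap@voxels[object@validMask@voxels > 0]
  cat("FitResult (", object@method, "): ", sum(object@validMask@voxels),
      " valid voxels", sep = "")
  if (length(v)) cat(sprintf(", Tb median %.3g ms", stats::median(v)))
  cat("\n")
})

setMethod("show", "CartilageSurfaces", function(object) {
  cat("CartilageSurfaces:", nrow(object@subchondral), "subchondral /",
      nrow(object@articular), "articular points\n")
  if (length(object@thickness))
    cat(sprintf("  thickness mean %.3f mm (sd %.3f)\n",
                mean(object@thickness), stats::sd(object@thickness)))
})

#' Number of records in an ImageList
#' @param x an [ImageList-class].
#' @export
setMethod("length", "ImageList", function(x) nrow(x@records))

#' Records of an ImageList
#' @param x an [ImageList-class].
#' @return data.frame of records.
#' @export
imageRecords <- function(x) {
  stopifnot(is(x, "ImageList"))
  x@records
}
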