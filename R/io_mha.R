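# MetaImage (.mha, local-data) reader/writer.
# The header is ASCII "Key = value" lines followed by the raw voxel block,
# x fastest, little endian. TransformMatrix rows are the axis direction
# cosines (the transpose of the direction matrix used in this package).

.met_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_UINT   = list(what = "integer", size = 4L, signed = TRUE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE))

.read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("truncated MetaImage header in ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3) stop("malformed MetaImage header line: ", line)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  if (!identical(hdr$NDims, "3"))
    stop("only 3D MetaImage volumes are supported (NDims = ",
         hdr$NDims %||% "?", ")")
  if (!is.null(hdr$CompressedData) &&
      tolower(hdr$CompressedData) == "true")
    stop("compressed MetaImage data is not supported; write uncompressed .mha")
  if (!is.null(hdr$BinaryDataByteOrderMSB) &&
      tolower(hdr$BinaryDataByteOrderMSB) == "true")
    stop("big-endian MetaImage data is not supported")
  if (!identical(hdr$ElementDataFile, "LOCAL"))
    stop("only ElementDataFile = LOCAL .mha files are supported")
  typ <- .met_types[[hdr$ElementType]]
  if (is.null(typ)) stop("unsupported ElementType: ", hdr$ElementType)
  dm <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  org <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  tm <- as.numeric(strsplit(hdr$TransformMatrix %||% "1 0 0 0 1 0 0 0 1",
                            "\\s+")[[1]])
  dirmat <- t(matrix(tm, 3, 3, byrow = TRUE)) # rows -> columns
  n <- prod(dm)
  vox <- readBin(con, what = typ$what, n = n, size = typ$size,
                 signed = typ$signed, endian = "little")
  if (length(vox) != n) stop("truncated MetaImage voxel data in ", path)
  arr <- array(as.double(vox), dim = dm)
  Image3D(arr, spacing = sp, origin = org, direction = dirmat)
}

#' Read a 3D image volume
#'
#' Reads a MetaImage file (`.mha`, local uncompressed data) or a directory
#' containing exactly one DICOM series. DICOM slices are ordered by their
#' spatial position along the slice normal, never by filename; inconsistent
#' slice spacing (beyond 1e-3 mm) or mixed series in one directory are
#' rejected with a message naming the offending slices.
#'
#' @param path path to a `.mha` file or to a DICOM directory.
#' @return An [Image3D-class]. Voxel geometry is taken from file metadata;
#'   no reorientation is applied on read (standardization is explicit, see
#'   [orientToRAI()]).
#' @seealso [writeImage()], [readDicomSeries()] for multi-echo series.
#' @export
readImage <- function(path) {
  if (dir.exists(path)) {
    vols <- readDicomSeries(path)
    if (length(vols) != 1L)
      stop("directory ", path, " holds ", length(vols), " echo/spin-lock ",
           "volumes; use readDicomSeries() for multi-echo data")
    return(vols[[1L]])
  }
  if (!file.exists(path)) stop("cannot read image: ", path, " does not exist")
  if (!grepl("\\.mha$", path, ignore.case = TRUE))
    stop("unsupported image format: ", path, " (expected .mha or a DICOM ",
         "directory)")
  .read_mha(path)
}

#' Write an image or mask as MetaImage (.mha)
#'
#' Images are written as 64-bit floats so that read-back voxels are
#' bit-identical; [BinaryMask-class] objects are written as 8-bit unsigned
#' with values \{0, 1\}. Full geometry (spacing, origin, direction) is stored
#' in the header.
#'
#' @param image an [Image3D-class] or [BinaryMask-class].
#' @param path output path ending in `.mha`; the parent directory is created
#'   when missing.
#' @return `path`, invisibly.
#' @export
writeImage <- function(image, path) {
  stopifnot(is(image, "Image3D"))
  if (any(!is.finite(image@voxels)))
    stop("refusing to write image with non-finite (NaN/Inf/NA) voxels")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dirname(path)))
    stop("cannot create output directory for ", path)
  is_mask <- is(image, "BinaryMask")
  etype <- if (is_mask) "MET_UCHAR" else "MET_DOUBLE"
  dm <- dim(image@voxels)
  tm <- t(image@direction) # rows = axis directions
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =",
          paste(format(as.vector(t(tm)), digits = 17, trim = TRUE,
                       scientific = FALSE), collapse = " ")),
    paste("Offset =", paste(format(image@origin, digits = 17, trim = TRUE,
                                   scientific = FALSE), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =", paste(format(image@spacing, digits = 17,
                                           trim = TRUE, scientific = FALSE),
                                    collapse = " ")),
    paste("DimSize =", paste(dm, collapse = " ")),
    paste("ElementType =", etype),
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (is_mask) {
    writeBin(as.integer(image@voxels), con, size = 1L, endian = "little")
  } else {
    writeBin(as.double(image@voxels), con, size = 8L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
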