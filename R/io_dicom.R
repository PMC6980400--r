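# Minimal DICOM series reader: uncompressed single-frame grayscale slices,
# implicit or explicit VR little endian. Slices are assembled into volumes
# by spatial position along the slice normal; multi-echo series are split by
# echo time with volumes returned in ascending acquisition time.

.u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
.u32 <- function(raw, pos) {
  as.integer(raw[pos]) + 256 * as.integer(raw[pos + 1L]) +
    65536 * as.integer(raw[pos + 2L]) + 16777216 * as.integer(raw[pos + 3L])
}

.dcm_tag <- function(g, e) sprintf("%04X%04X", g, e)

# DICOM string value: drop NUL padding bytes, trim spaces
.raw_str <- function(val) trimws(rawToChar(val[val != as.raw(0)]))

# VRs with a 2-byte reserved field and 4-byte length in explicit encoding
.long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN", "UC", "UR")

# skip an undefined-length sequence/item body; returns position after the
# matching delimiter. Explicit/implicit agnostic: items are (FFFE,E000),
# delimiters (FFFE,E00D)/(FFFE,E0DD) which are always implicit-form.
.skip_undefined <- function(raw, pos) {
  repeat {
    if (pos + 7L > length(raw)) stop("truncated DICOM sequence")
    g <- .u16(raw, pos); e <- .u16(raw, pos + 2L)
    len <- .u32(raw, pos + 4L)
    pos <- pos + 8L
    if (g == 0xFFFE && e == 0xE0DD) return(pos)          # sequence delimiter
    if (g == 0xFFFE && e == 0xE00D) return(pos)          # item delimiter
    if (g == 0xFFFE && e == 0xE000) {                    # item
      if (len == 0xFFFFFFFF) pos <- .skip_undefined(raw, pos)
      else pos <- pos + len
    } else {
      stop("unexpected tag inside undefined-length DICOM sequence")
    }
  }
}

# parse one DICOM file; returns a named list of the tags the workflow needs
.read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  # file meta group (always explicit little endian)
  transfer <- "1.2.840.10008.1.2.1"
  meta_end <- NA_integer_
  repeat {
    g <- .u16(raw, pos)
    if (g != 2L) break
    e <- .u16(raw, pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% .long_vrs) {
      len <- .u32(raw, pos + 8L); vpos <- pos + 12L
    } else {
      len <- .u16(raw, pos + 6L); vpos <- pos + 8L
    }
    val <- raw[vpos:(vpos + len - 1L)]
    if (e == 0x0000) meta_end <- vpos + len + .u32(raw, vpos) - 1L
    if (e == 0x0010) transfer <- .raw_str(val)
    pos <- vpos + len
    if (!is.na(meta_end) && pos > meta_end) break
  }
  explicit <- switch(transfer,
    "1.2.840.10008.1.2" = FALSE,
    "1.2.840.10008.1.2.1" = TRUE,
    stop("unsupported DICOM transfer syntax ", transfer, " in ", path,
         " (only implicit/explicit VR little endian, uncompressed)"))
  out <- list(path = path)
  n <- length(raw)
  while (pos + 7L <= n) {
    g <- .u16(raw, pos); e <- .u16(raw, pos + 2L)
    vr <- NULL
    if (g == 0xFFFE) { # delimiters at top level: shouldn't happen, skip
      pos <- pos + 8L
      next
    }
    if (explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% .long_vrs) {
        len <- .u32(raw, pos + 8L); vpos <- pos + 12L
      } else {
        len <- .u16(raw, pos + 6L); vpos <- pos + 8L
      }
    } else {
      len <- .u32(raw, pos + 4L); vpos <- pos + 8L
    }
    if (len == 0xFFFFFFFF) { # undefined length (sequences)
      pos <- .skip_undefined(raw, vpos)
      next
    }
    tag <- .dcm_tag(g, e)
    if (tag == "7FE00010") {
      out$pixel_raw <- raw[vpos:(vpos + len - 1L)]
      break
    }
    if (tag %in% c("00080060", "0008103E", "0020000E", "00200032",
                   "00200037", "00280010", "00280011", "00280030",
                   "00180050", "00180081", "00280100", "00280103",
                   "00281052", "00281053")) {
      val <- raw[seq_len(len) + vpos - 1L]
      out[[tag]] <- if (tag %in% c("00280010", "00280011", "00280100",
                                   "00280103")) {
        .u16(val, 1L)
      } else {
        .raw_str(val)
      }
    }
    # skip sequence bodies with defined length too
    pos <- vpos + len
  }
  if (is.null(out$pixel_raw)) stop("no pixel data found in ", path)
  out
}

.dcm_nums <- function(s) as.numeric(strsplit(s, "\\\\")[[1]])

.dcm_slice_matrix <- function(f) {
  rows <- f[["00280010"]]; cols <- f[["00280011"]]
  bits <- f[["00280100"]] %||% 16L
  signed <- identical(f[["00280103"]], 1L)
  if (!bits %in% c(8L, 16L))
    stop("unsupported BitsAllocated (", bits, ") in ", f$path)
  npix <- rows * cols
  v <- readBin(f$pixel_raw, what = "integer", n = npix,
               size = bits %/% 8L, signed = if (bits == 8L) FALSE else signed,
               endian = "little")
  if (bits == 16L && !signed) v <- ifelse(v < 0, v + 65536, v)
  slope <- as.numeric(f[["00281053"]] %||% "1")
  inter <- as.numeric(f[["00281052"]] %||% "0")
  # pixel data is row-major: first index (columns) fastest
  matrix(v * slope + inter, nrow = cols, ncol = rows)
}

#' Read a DICOM directory as one or more volumes
#'
#' All DICOM files in `path` must belong to a single series (one
#' SeriesInstanceUID). Slices are sorted by the projection of
#' ImagePositionPatient onto the slice normal (the cross product of the two
#' in-plane direction cosines) -- never by filename. When several echo times
#' are present (multi-echo / multi-spin-lock acquisitions) one volume per
#' time is returned, in ascending acquisition time.
#'
#' @param path directory containing the `.dcm` files of one series.
#' @return A list of [Image3D-class] volumes with an `"times"` attribute
#'   (ms; NA when the series carries no echo time).
#' @export
readDicomSeries <- function(path) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no files found in DICOM directory ", path)
  slices <- lapply(files, .read_dicom_file)
  uids <- unique(vapply(slices, function(f) f[["0020000E"]] %||% "",
                        character(1)))
  if (length(uids) > 1L)
    stop("directory ", path, " contains ", length(uids),
         " DICOM series; split them into one directory per series")
  times <- vapply(slices, function(f)
    as.numeric(f[["00180081"]] %||% NA_real_), numeric(1))
  groups <- split(seq_along(slices),
                  factor(ifelse(is.na(times), "NA", format(times))))
  utimes <- vapply(groups, function(i) times[i[1]], numeric(1))
  ord <- order(utimes, na.last = TRUE)
  vols <- lapply(groups[ord], function(idx) .assemble_volume(slices[idx]))
  attr(vols, "times") <- unname(utimes[ord])
  vols
}

.assemble_volume <- function(slices) {
  iop <- .dcm_nums(slices[[1]][["00200037"]] %||% "1\\0\\0\\0\\1\\0")
  rdir <- iop[1:3]; cdir <- iop[4:6]
  normal <- c(rdir[2] * cdir[3] - rdir[3] * cdir[2],
              rdir[3] * cdir[1] - rdir[1] * cdir[3],
              rdir[1] * cdir[2] - rdir[2] * cdir[1])
  ipps <- t(vapply(slices, function(f)
    .dcm_nums(f[["00200032"]] %||% "0\\0\\0"), numeric(3)))
  proj <- as.vector(ipps %*% normal)
  ord <- order(proj)
  slices <- slices[ord]; ipps <- ipps[ord, , drop = FALSE]
  proj <- proj[ord]
  nz <- length(slices)
  if (nz > 1L) {
    dz <- diff(proj)
    if (any(dz <= 0))
      stop("duplicate slice positions in DICOM series (files ",
           paste(basename(vapply(slices, `[[`, "", "path"))[
             which(dz <= 0) + 1L], collapse = ", "), ")")
    if (max(dz) - min(dz) > 1e-3)
      stop("inconsistent DICOM slice spacing (range ",
           format(min(dz)), " .. ", format(max(dz)), " mm); offending ",
           "slices: ",
           paste(basename(vapply(slices, `[[`, "", "path"))[
             c(which.min(dz), which.max(dz)) + 1L], collapse = ", "))
    sz <- mean(dz)
  } else {
    sz <- as.numeric(slices[[1]][["00180050"]] %||% "1")
  }
  psp <- .dcm_nums(slices[[1]][["00280030"]] %||% "1\\1")
  # PixelSpacing is (row spacing, column spacing): y then x
  sp <- c(psp[2], psp[1], sz)
  mats <- lapply(slices, .dcm_slice_matrix)
  d1 <- dim(mats[[1]])
  arr <- array(0, c(d1[1], d1[2], nz))
  for (k in seq_len(nz)) arr[, , k] <- mats[[k]]
  dirmat <- cbind(rdir, cdir, normal)
  dimnames(dirmat) <- NULL
  Image3D(arr, spacing = sp, origin = ipps[1, ], direction = dirmat,
          modality = slices[[1]][["00080060"]] %||% "")
}
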