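# Minimal DICOM slice writer (explicit VR little endian, uncompressed
# 16-bit grayscale) used only to build reader fixtures. DICOM writing is
# deliberately not part of the package API.

.dcm_u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                    endian = "little")
.dcm_u32raw <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                    endian = "little")

.dcm_pad <- function(raw, padByte = as.raw(0x20)) {
  if (length(raw) %% 2L == 1L) c(raw, padByte) else raw
}

.dcm_element <- function(group, elem, vr, value) {
  if (is.character(value)) {
    pad <- if (vr == "UI") as.raw(0) else as.raw(0x20)
    value <- .dcm_pad(charToRaw(value), pad)
  }
  head <- c(.dcm_u16raw(group), .dcm_u16raw(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(head, as.raw(c(0, 0)), .dcm_u32raw(length(value)), value)
  } else {
    c(head, .dcm_u16raw(length(value)), value)
  }
}

# pixels: integer matrix (ncol x nrow layout, x fastest) of 16-bit values
write_dicom_slice <- function(path, pixels, ipp, iop = c(1, 0, 0, 0, 1, 0),
                              pixelSpacing = c(0.5, 0.5),
                              sliceThickness = 1,
                              seriesUID = "1.2.3.4.5", echoTime = NULL) {
  nx <- nrow(pixels); ny <- ncol(pixels)
  body <- c(
    .dcm_element(0x0008, 0x0060, "CS", "MR"),
    .dcm_element(0x0018, 0x0050, "DS", format(sliceThickness)),
    if (!is.null(echoTime))
      .dcm_element(0x0018, 0x0081, "DS", format(echoTime)),
    .dcm_element(0x0020, 0x000E, "UI", seriesUID),
    .dcm_element(0x0020, 0x0032, "DS",
                 paste(format(ipp), collapse = "\\")),
    .dcm_element(0x0020, 0x0037, "DS",
                 paste(format(iop), collapse = "\\")),
    .dcm_element(0x0028, 0x0010, "US", .dcm_u16raw(ny)), # rows
    .dcm_element(0x0028, 0x0011, "US", .dcm_u16raw(nx)), # columns
    .dcm_element(0x0028, 0x0030, "DS",
                 paste(format(pixelSpacing[c(2, 1)]), collapse = "\\")),
    .dcm_element(0x0028, 0x0100, "US", .dcm_u16raw(16L)),
    .dcm_element(0x0028, 0x0103, "US", .dcm_u16raw(0L)),
    .dcm_element(0x7FE0, 0x0010, "OW",
                 writeBin(as.integer(as.vector(pixels)), raw(), size = 2L,
                          endian = "little")))
  ts <- .dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  meta <- c(.dcm_element(0x0002, 0x0000, "UL", .dcm_u32raw(length(ts))), ts)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(rep(as.raw(0), 128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# write a whole volume as one slice file per z, optionally shuffling names
write_dicom_volume <- function(dir, vol, spacing = c(0.5, 0.5, 1),
                               origin = c(0, 0, 0), shuffle = FALSE,
                               echoTime = NULL, seriesUID = "1.2.3.4.5",
                               prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- dim(vol)[3]
  ord <- if (shuffle) sample(nz) else seq_len(nz)
  for (fi in seq_len(nz)) {
    k <- ord[fi]
    write_dicom_slice(
      file.path(dir, sprintf("%sslice%02d.dcm", prefix, fi)),
      matrix(as.integer(vol[, , k]), dim(vol)[1], dim(vol)[2]),
      ipp = c(origin[1], origin[2], origin[3] + (k - 1) * spacing[3]),
      pixelSpacing = spacing[1:2], sliceThickness = spacing[3],
      echoTime = echoTime, seriesUID = seriesUID)
  }
  invisible(dir)
}
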