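# Plain-text image list parsing.
#
# Dialect (defined by this package's documentation): one record per line,
# fields separated by whitespace or commas, '#' starts a comment, blank lines
# ignored. Fields, in order:
#   image_path  [femur_mask_path]  [cartilage_mask_path]  [laterality]  [role]
# A lone '-' marks an absent optional path. laterality is 'left' or 'right'
# (default 'left'); role is 'reference', 'moving' or 'ground_truth'
# (default 'moving'). Relative paths resolve against the list file's folder.

#' Parse a plain-text image list
#'
#' @param path path to the list file.
#' @param checkExists verify that every referenced path resolves before a run
#'   starts (default TRUE).
#' @return An [ImageList-class], record order preserved.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("# cohort", "img1.mha - - left moving"), f)
#' parseImageList(f, checkExists = FALSE)
#' @export
parseImageList <- function(path, checkExists = TRUE) {
  if (!file.exists(path)) stop("image list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  base <- dirname(normalizePath(path))
  recs <- list()
  for (ln in seq_along(lines)) {
    txt <- sub("#.*$", "", lines[ln])
    txt <- trimws(txt)
    if (!nzchar(txt)) next
    fields <- strsplit(txt, "[,[:space:]]+")[[1]]
    if (length(fields) > 5L)
      stop("malformed image list line ", ln, ": more than 5 fields")
    get <- function(i, default) {
      if (length(fields) >= i && fields[i] != "-") fields[i] else default
    }
    lat <- get(4L, "left")
    if (!lat %in% c("left", "right"))
      stop("unknown laterality token '", lat, "' on line ", ln,
           " of ", path, " (expected left or right)")
    role <- get(5L, "moving")
    if (!role %in% c("reference", "moving", "ground_truth"))
      stop("unknown role token '", role, "' on line ", ln, " of ", path)
    resolve <- function(p) {
      if (is.na(p)) return(NA_character_)
      if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
      p
    }
    recs[[length(recs) + 1L]] <- data.frame(
      image_path = resolve(get(1L, NA_character_)),
      femur_mask_path = resolve(get(2L, NA_character_)),
      cartilage_mask_path = resolve(get(3L, NA_character_)),
      laterality = lat, role = role, line = ln,
      stringsAsFactors = FALSE)
  }
  df <- if (length(recs)) do.call(rbind, recs) else
    data.frame(image_path = character(), femur_mask_path = character(),
               cartilage_mask_path = character(), laterality = character(),
               role = character(), line = integer(),
               stringsAsFactors = FALSE)
  if (checkExists && nrow(df)) {
    for (r in seq_len(nrow(df))) {
      for (col in c("image_path", "femur_mask_path", "cartilage_mask_path")) {
        p <- df[[col]][r]
        if (!is.na(p) && !file.exists(p))
          stop("image list line ", df$line[r], ": ", col, " '", p,
               "' does not exist")
      }
    }
  }
  new("ImageList", records = df[setdiff(names(df), "line")])
}

#' Build an ImageList from paths
#'
#' Programmatic counterpart of [parseImageList()].
#'
#' @param image_path character vector of image paths.
#' @param femur_mask_path,cartilage_mask_path optional mask paths (NA when
#'   absent).
#' @param laterality,role per-record tokens, recycled.
#' @return An [ImageList-class].
#' @export
imageList <- function(image_path, femur_mask_path = NA_character_,
                      cartilage_mask_path = NA_character_,
                      laterality = "left", role = "moving") {
  if (!length(image_path))
    return(new("ImageList", records = data.frame(
      image_path = character(), femur_mask_path = character(),
      cartilage_mask_path = character(), laterality = character(),
      role = character(), stringsAsFactors = FALSE)))
  df <- data.frame(image_path = image_path,
                   femur_mask_path = femur_mask_path,
                   cartilage_mask_path = cartilage_mask_path,
                   laterality = laterality, role = role,
                   stringsAsFactors = FALSE)
  new("ImageList", records = df)
}

#' Write an ImageList to its text format
#'
#' @param x an [ImageList-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeImageList <- function(x, path) {
  stopifnot(is(x, "ImageList"))
  df <- x@records
  na2dash <- function(v) ifelse(is.na(v), "-", v)
  lines <- sprintf("%s %s %s %s %s", na2dash(df$image_path),
                   na2dash(df$femur_mask_path),
                   na2dash(df$cartilage_mask_path), df$laterality, df$role)
  writeLines(lines, path)
  invisible(path)
}
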