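# Atlas-based femoral cartilage segmentation: reference selection by
# deformation-field convergence, mask propagation through inverted
# registrations, and quality metrics (Dice overlap, average surface
# distance).

.mode_models <- function(mode) {
  switch(mode,
         intersubject = c("rigid", "similarity", "bspline"),
         longitudinal = c("rigid", "bspline"),
         multimodal = "rigid",
         stop("unknown segmentation mode '", mode,
              "' (expected intersubject, longitudinal or multimodal)"))
}

#' Select the reference (atlas) image by deformation-field convergence
#'
#' Starting from a seed image, every image of the dataset is registered to
#' the current reference (rigid + similarity + B-spline); the resulting
#' displacement fields are averaged inside the reference femur mask and the
#' image whose field is closest to the average (mean Euclidean distance)
#' becomes the next reference. Iteration stops when two consecutive
#' iterations choose the same reference, or after `maxIterations`. Ties pick
#' the lowest image index. Femur masks are required for every image: the
#' field comparison is computed in the femur volume because the cartilage
#' volume alone is too small.
#'
#' @param images list of preprocessed [Image3D-class] volumes.
#' @param femurMasks list of [BinaryMask-class] femur masks, one per image,
#'   each on its image's geometry.
#' @param seedIndex index of the initial reference.
#' @param maxIterations iteration cap (default 10).
#' @param control a [regControl()] list.
#' @return list with `referenceIndex`, `converged`, and `state`: a data.frame
#'   trace (iteration, reference, per-image field distance in mm, chosen).
#' @export
findReference <- function(images, femurMasks, seedIndex = 1L,
                          maxIterations = 10L, control = regControl()) {
  n <- length(images)
  if (n == 0L) stop("dataset is empty")
  if (length(femurMasks) != n || any(vapply(femurMasks, is.null, logical(1))))
    stop("findReference requires a femur mask for every image")
  if (n == 1L)
    return(list(referenceIndex = 1L, converged = TRUE,
                state = data.frame(iteration = 1L, reference = seedIndex,
                                   image = 1L, distance_mm = 0,
                                   chosen = TRUE)))
  ref <- as.integer(seedIndex)
  trace <- list()
  converged <- FALSE
  for (iter in seq_len(maxIterations)) {
    refimg <- images[[ref]]
    refmask <- femurMasks[[ref]]
    fields <- vector("list", n)
    ok <- rep(TRUE, n)
    for (i in seq_len(n)) {
      if (i == ref) {
        fields[[i]] <- renderField(identityChain(geometry(refimg)))
        next
      }
      ch <- withCallingHandlers(
        registerImages(refimg, images[[i]],
                       models = c("rigid", "similarity", "bspline"),
                       focusMask = refmask, control = control),
        warning = function(w) invokeRestart("muffleWarning"))
      if (ch@failed) {
        ok[i] <- FALSE
        warning("registration of image ", i, " to reference ", ref,
                " failed; image excluded from this iteration")
        next
      }
      fields[[i]] <- renderField(ch)
    }
    avg <- averageFields(fields[ok], refmask)
    dist <- rep(NA_real_, n)
    for (i in which(ok))
      dist[i] <- fieldDistance(fields[[i]], avg, refmask)
    nxt <- which(dist == min(dist, na.rm = TRUE))[1L] # tie: lowest index
    trace[[iter]] <- data.frame(iteration = iter, reference = ref,
                                image = seq_len(n), distance_mm = dist,
                                chosen = seq_len(n) == nxt)
    if (nxt == ref) { converged <- TRUE; break }
    ref <- nxt
  }
  list(referenceIndex = ref, converged = converged,
       state = do.call(rbind, trace))
}

#' Segment femoral cartilage by atlas propagation
#'
#' Registers the target image to the reference with the mode's model list
#' (intersubject: rigid + similarity + B-spline; longitudinal: rigid +
#' B-spline; multimodal: rigid only), inverts the chain, and warps the
#' reference cartilage mask onto the target geometry with nearest-neighbour
#' interpolation. The multimodal mode defaults to the mutual-information
#' metric.
#'
#' @param reference preprocessed reference [Image3D-class].
#' @param referenceCartilage [BinaryMask-class] cartilage mask of the
#'   reference (on the reference geometry).
#' @param target preprocessed target [Image3D-class].
#' @param mode "intersubject", "longitudinal" or "multimodal".
#' @param referenceFemur optional [BinaryMask-class] femur mask of the
#'   reference used as registration focus.
#' @param control a [regControl()] list; for multimodal the metric defaults
#'   to "mi" unless explicitly set.
#' @return list with `mask` ([BinaryMask-class] on the target geometry),
#'   `stagesApplied` (character vector of registration models), `failed`,
#'   `emptyOutput`, and `chain` (the forward [TransformChain-class]).
#' @export
segmentCartilage <- function(reference, referenceCartilage, target,
                             mode = c("intersubject", "longitudinal",
                                      "multimodal"),
                             referenceFemur = NULL, control = NULL) {
  mode <- match.arg(mode)
  models <- .mode_models(mode)
  if (is.null(control))
    control <- if (mode == "multimodal") regControl(metric = "mi")
               else regControl()
  if (!sameGeometry(geometry(referenceCartilage), geometry(reference)))
    .stop_geometry_mismatch("reference image and cartilage mask")
  chain <- registerImages(reference, target, models = models,
                          focusMask = referenceFemur,
                          cartilageFocus =
                            if ("bspline" %in% models) referenceCartilage
                            else NULL,
                          control = control)
  inv <- invertTransform(chain, geometry(target))
  mask <- warpMask(referenceCartilage, inv, geometry(target))
  empty <- sum(mask@voxels) == 0
  if (empty)
    warning("segmentation produced an empty mask; flagged as failed")
  list(mask = mask, stagesApplied = models, mode = mode,
       failed = chain@failed || empty, emptyOutput = empty, chain = chain)
}

#' Dice similarity coefficient
#'
#' Overlap between a newly segmented mask NM and a ground-truth mask GT:
#' \deqn{DSC = 2 |NM \cap GT| / (|NM| + |GT|)}
#' Symmetric in its arguments; 1 for identical nonempty masks, 0 for
#' disjoint masks. Two empty masks are an error (the coefficient is
#' undefined), not 0.
#'
#' @param nm,gt [BinaryMask-class] on identical geometry.
#' @return DSC in [0, 1].
#' @export
dice <- function(nm, gt) {
  stopifnot(is(nm, "BinaryMask"), is(gt, "BinaryMask"))
  if (!sameGeometry(geometry(nm), geometry(gt)))
    .stop_geometry_mismatch("masks")
  a <- sum(nm@voxels); b <- sum(gt@voxels)
  if (a + b == 0) stop("Dice coefficient is undefined for two empty masks")
  2 * sum(nm@voxels * gt@voxels) / (a + b)
}

# 0-based index matrix of 6-connectivity boundary voxels (foreground voxel
# with at least one background face neighbour; grid border counts)
.boundary_indices <- function(arr) {
  d <- dim(arr)
  fg <- arr > 0
  interior <- array(TRUE, d)
  shift_and <- function(acc, ax, dir) {
    nb <- array(FALSE, d)
    if (ax == 1) {
      if (dir > 0) nb[-d[1], , ] <- fg[-1, , ] else nb[-1, , ] <- fg[-d[1], , ]
    } else if (ax == 2) {
      if (dir > 0) nb[, -d[2], ] <- fg[, -1, ] else nb[, -1, ] <- fg[, -d[2], ]
    } else {
      if (dir > 0) nb[, , -d[3]] <- fg[, , -1] else nb[, , -1] <- fg[, , -d[3]]
    }
    acc & nb
  }
  for (ax in 1:3) for (dir in c(-1, 1))
    interior <- shift_and(interior, ax, dir)
  which(fg & !interior, arr.ind = TRUE) - 1
}

#' Average surface distance (mm)
#'
#' Boundary voxels (6-connectivity face boundary) are extracted from both
#' masks; for each boundary voxel of each mask the minimum Euclidean distance
#' (between voxel centers, in physical mm) to the other mask's boundary is
#' taken, and the two directed sums are divided by the total number of
#' boundary voxels:
#' \deqn{ASD = (\sum_i \min_j d_{ij} + \sum_j \min_i d_{ij}) /
#'   (n_{nm} + n_{gt})}
#' Symmetric; scaling the voxel spacing by s scales the ASD by s.
#'
#' @param nm,gt nonempty [BinaryMask-class] on identical geometry.
#' @return ASD in mm.
#' @export
averageSurfaceDistance <- function(nm, gt) {
  stopifnot(is(nm, "BinaryMask"), is(gt, "BinaryMask"))
  if (!sameGeometry(geometry(nm), geometry(gt)))
    .stop_geometry_mismatch("masks")
  if (sum(nm@voxels) == 0 || sum(gt@voxels) == 0)
    stop("average surface distance requires two nonempty masks")
  bn <- indexToPhysical(geometry(nm), .boundary_indices(nm@voxels))
  bg <- indexToPhysical(geometry(gt), .boundary_indices(gt@voxels))
  dn <- cpp_min_dists(bn, bg)
  dg <- cpp_min_dists(bg, bn)
  (sum(dn) + sum(dg)) / (nrow(bn) + nrow(bg))
}

#' Evaluate a batch of segmentation/ground-truth pairs
#'
#' One quality row per pair (Dice, ASD, failure flag); per-pair errors are
#' recorded as failed rows with NA metrics and the batch continues. The
#' summary (mean and population-free SD over valid rows) is appended as two
#' rows with image_id "mean" and "sd".
#'
#' @param pairs list of lists with elements `nm`, `gt` ([BinaryMask-class])
#'   and optional `id`.
#' @param failureThreshold rows with DSC below this are flagged failed
#'   (default 0.6, chosen to separate the rare gross registration failures
#'   from ordinary segmentations).
#' @param file optional CSV path; written with the summary rows.
#' @return data.frame (image_id, dsc, asd, failed) with attribute "summary".
#' @export
evaluateBatch <- function(pairs, failureThreshold = 0.6, file = NULL) {
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    id <- p$id %||% as.character(i)
    out <- tryCatch({
      d <- dice(p$nm, p$gt)
      a <- averageSurfaceDistance(p$nm, p$gt)
      data.frame(image_id = id, dsc = d, asd = a,
                 failed = d < failureThreshold, stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(image_id = id, dsc = NA_real_, asd = NA_real_,
                 failed = TRUE, stringsAsFactors = FALSE))
    out
  })
  df <- do.call(rbind, rows)
  valid <- df[!df$failed & !is.na(df$dsc), , drop = FALSE]
  summ <- data.frame(
    image_id = c("mean", "sd"),
    dsc = c(mean(valid$dsc), stats::sd(valid$dsc)),
    asd = c(mean(valid$asd), stats::sd(valid$asd)),
    failed = NA, stringsAsFactors = FALSE)
  attr(df, "summary") <- summ
  if (!is.null(file)) {
    utils::write.csv(rbind(df, summ), file, row.names = FALSE)
  }
  df
}
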