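# Cartilage morphology: per-slice sub-voxel contour extraction, separation
# of the subchondral (bone-facing) from the articular (joint-facing) side,
# cylinder-fit flattening for 2D thickness maps, 3D nearest-neighbour
# thickness and voxel-count volume.

#' Extract per-slice cartilage contours as a point cloud
#'
#' Slices the mask along the medial-lateral (sagittal stack) axis and traces
#' the 0.5 iso-contour of each nonempty slice (marching-squares style, via
#' [grDevices::contourLines()]), giving ordered boundary point sequences at
#' sub-voxel precision in physical mm.
#'
#' @param mask a nonempty [BinaryMask-class].
#' @param sliceAxis axis index of the sagittal stack (default 1, the
#'   left-right axis of the canonical RAI frame).
#' @return list of contours; each element is a list with `slice` (1-based
#'   slice index) and `points` (ordered n x 3 matrix, physical mm).
#' @export
extractContours <- function(mask, sliceAxis = 1L) {
  stopifnot(is(mask, "BinaryMask"), sliceAxis %in% 1:3)
  if (sum(mask@voxels) == 0) stop("cannot extract contours of an empty mask")
  g <- geometry(mask)
  d <- g$dim
  inplane <- setdiff(1:3, sliceAxis)
  out <- list()
  for (s in seq_len(d[sliceAxis])) {
    m <- switch(sliceAxis, mask@voxels[s, , ], mask@voxels[, s, ],
                mask@voxels[, , s])
    if (!any(m > 0)) next
    da <- dim(m)
    padded <- matrix(0, da[1] + 2L, da[2] + 2L)
    padded[2:(da[1] + 1L), 2:(da[2] + 1L)] <- m
    cls <- grDevices::contourLines(x = seq(-1, da[1]), y = seq(-1, da[2]),
                                   z = padded, levels = 0.5)
    for (cl in cls) {
      n <- length(cl$x)
      idx <- matrix(0, n, 3)
      idx[, sliceAxis] <- s - 1
      idx[, inplane[1]] <- cl$x
      idx[, inplane[2]] <- cl$y
      out[[length(out) + 1L]] <- list(slice = s,
                                      points = indexToPhysical(g, idx))
    }
  }
  out
}

# Kasa algebraic circle fit on 2D points; returns center (2) and radius
.fit_circle <- function(uv) {
  if (nrow(uv) < 3L) {
    ctr <- colMeans(uv)
    return(list(center = ctr,
                radius = mean(sqrt(rowSums(sweep(uv, 2, ctr)^2)))))
  }
  X <- cbind(uv, 1)
  y <- rowSums(uv^2)
  beta <- tryCatch(stats::lm.fit(X, y)$coefficients,
                   error = function(e) rep(NA_real_, 3))
  if (any(is.na(beta))) { # collinear points: fall back to centroid
    ctr <- colMeans(uv)
    return(list(center = ctr,
                radius = mean(sqrt(rowSums(sweep(uv, 2, ctr)^2)))))
  }
  ctr <- beta[1:2] / 2
  r2 <- beta[3] + sum(ctr^2)
  list(center = ctr, radius = sqrt(max(r2, 0)))
}

#' Separate the subchondral from the articular cartilage side
#'
#' Per slice, a circle is fitted (algebraic least squares) to all contour
#' points; points are classified by their radius from the fitted center:
#' the inner (smaller-radius, bone-facing) cluster is subchondral, the outer
#' is articular. End caps and side-connecting segments are trimmed by
#' dropping points whose radial classification margin is below 25% of the
#' estimated wall thickness. Non-annular slices (no radial bimodality) fall
#' back to a plain median-radius split with a warning.
#'
#' @param contours output of [extractContours()].
#' @param sliceAxis axis index used for slicing.
#' @return list with `subchondral` and `articular` point matrices (n x 3,
#'   mm); the two clouds partition the retained contour points.
#' @export
splitSides <- function(contours, sliceAxis = 1L) {
  if (!length(contours)) stop("no contours to split")
  inplane <- setdiff(1:3, sliceAxis)
  slices <- split(contours, vapply(contours, `[[`, 0, "slice"))
  sub <- list(); art <- list()
  warned <- FALSE
  for (sl in slices) {
    pts <- do.call(rbind, lapply(sl, `[[`, "points"))
    uv <- pts[, inplane, drop = FALSE]
    fit <- .fit_circle(uv)
    r <- sqrt(rowSums(sweep(uv, 2, fit$center)^2))
    if (length(unique(round(r, 9))) < 2L) next
    km <- suppressWarnings(stats::kmeans(r, centers = range(r)))
    cen <- sort(km$centers[, 1])
    wall <- cen[2] - cen[1]
    tau <- mean(cen)
    if (wall < 1e-6) {
      if (!warned) {
        warning("slice without radial shell structure; falling back to a ",
                "median-radius split")
        warned <- TRUE
      }
      tau <- stats::median(r)
      inner <- r <= tau
      keep <- rep(TRUE, length(r))
    } else {
      inner <- r < tau
      keep <- abs(r - tau) >= 0.25 * wall
      if (!any(keep & inner) || !any(keep & !inner))
        keep <- rep(TRUE, length(r)) # one-voxel walls: keep everything
    }
    sub[[length(sub) + 1L]] <- pts[keep & inner, , drop = FALSE]
    art[[length(art) + 1L]] <- pts[keep & !inner, , drop = FALSE]
  }
  subm <- do.call(rbind, sub)
  artm <- do.call(rbind, art)
  if (is.null(subm) || is.null(artm) || !nrow(subm) || !nrow(artm))
    stop("could not separate cartilage sides (degenerate contours)")
  list(subchondral = subm, articular = artm)
}

#' Flatten the subchondral surface by cylinder unrolling
#'
#' Fits a circle per slice to the subchondral points (axis along the slice
#' axis), pools the per-slice centers and radii, and maps each point to
#' (theta * r_mean, slice position): the angle theta is measured in the
#' in-plane coordinate frame from the second canonical axis (posterior
#' direction in RAI) and multiplied by the pooled radius to give an
#' arc-length abscissa in mm; the ordinate is the physical position along
#' the slice axis. The mapping is injective per slice for annular input.
#'
#' @param subchondral n x 3 matrix of subchondral points (mm).
#' @param sliceAxis axis index of the sagittal stack.
#' @return list with `flat` (n x 2 matrix, mm), `center` (pooled in-plane
#'   center), `radius` (pooled mean radius, mm).
#' @export
flattenCartilage <- function(subchondral, sliceAxis = 1L) {
  stopifnot(is.matrix(subchondral), ncol(subchondral) == 3)
  inplane <- setdiff(1:3, sliceAxis)
  spos <- subchondral[, sliceAxis]
  us <- unique(round(spos, 6))
  if (length(us) < 2L)
    stop("flattening requires subchondral points on at least 2 slices")
  centers <- list(); radii <- numeric(0)
  for (s in us) {
    sel <- abs(spos - s) < 1e-6
    if (sum(sel) < 3L) next
    fit <- .fit_circle(subchondral[sel, inplane, drop = FALSE])
    centers[[length(centers) + 1L]] <- fit$center
    radii <- c(radii, fit$radius)
  }
  if (!length(radii)) { # too few points per slice: pool across slices
    fit <- .fit_circle(subchondral[, inplane, drop = FALSE])
    centers <- list(fit$center); radii <- fit$radius
  }
  if (!length(radii) || !all(is.finite(radii)))
    stop("degenerate cylinder fit (collinear points)")
  ctr <- colMeans(do.call(rbind, centers))
  rmean <- mean(radii)
  duv <- sweep(subchondral[, inplane, drop = FALSE], 2, ctr)
  theta <- atan2(duv[, 2], duv[, 1])
  # place the branch cut inside the largest empty angular gap so a shell
  # spanning the +/-pi direction is not torn apart
  st <- sort(theta)
  gaps <- c(diff(st), st[1] + 2 * pi - st[length(st)])
  gi <- which.max(gaps)
  cut <- if (gi == length(st)) st[1] - gaps[gi] / 2
         else st[gi] + gaps[gi] / 2
  theta <- (theta - cut) %% (2 * pi) + cut
  flat <- cbind(theta * rmean, spos)
  colnames(flat) <- c("x_flat", "y_flat")
  list(flat = flat, center = ctr, radius = rmean)
}

#' Cartilage thickness by 3D nearest neighbour
#'
#' For each subchondral point, the Euclidean distance to its nearest
#' articular point in 3D physical space. This is the one-sided
#' subchondral-to-articular distance (thickness values are associated with
#' the subchondral cloud for 2D mapping); it is bounded above by the
#' symmetric Hausdorff distance. Only the nearest-neighbour algorithm is
#' implemented (`algo = "nn3d"`); the argument is a placeholder for
#' alternative thickness definitions.
#'
#' @param subchondral n x 3 matrix (mm).
#' @param articular nonempty m x 3 matrix (mm).
#' @param algo thickness algorithm; only "nn3d".
#' @return length-n vector of thicknesses (mm).
#' @export
cartilageThickness <- function(subchondral, articular, algo = "nn3d") {
  algo <- match.arg(algo, "nn3d")
  stopifnot(is.matrix(subchondral), is.matrix(articular))
  if (!nrow(articular)) stop("articular cloud is empty")
  cpp_min_dists(subchondral, articular)
}

#' Cartilage volume from a mask
#'
#' Number of foreground voxels multiplied by the voxel volume; an empty mask
#' has volume 0.
#'
#' @param mask a [BinaryMask-class].
#' @return volume in mm^3.
#' @examples
#' m <- BinaryMask(array(1, c(10, 10, 10)), spacing = c(0.3646, 0.3646, 0.7))
#' maskVolume(m)  # 1000 * 0.3646^2 * 0.7
#' @export
maskVolume <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  sum(mask@voxels) * prod(mask@spacing)
}

#' Full morphology analysis of a cartilage mask
#'
#' Contour extraction, side separation, flattening and thickness in one
#' call.
#'
#' @param mask a nonempty [BinaryMask-class].
#' @param sliceAxis sagittal-stack axis (default 1).
#' @return A [CartilageSurfaces-class]; the summary statistics (mean/sd
#'   thickness, volume) are available via [morphologySummary()].
#' @export
morphologyAnalysis <- function(mask, sliceAxis = 1L) {
  contours <- extractContours(mask, sliceAxis)
  sides <- splitSides(contours, sliceAxis)
  fl <- flattenCartilage(sides$subchondral, sliceAxis)
  th <- cartilageThickness(sides$subchondral, sides$articular)
  new("CartilageSurfaces", subchondral = sides$subchondral,
      articular = sides$articular, flatCoords = fl$flat, thickness = th,
      sliceAxis = as.numeric(sliceAxis))
}

#' Summary statistics of a morphology analysis
#'
#' @param surfaces a [CartilageSurfaces-class].
#' @param mask the analyzed [BinaryMask-class] (for the volume).
#' @return data.frame with mean_thickness_mm, sd_thickness_mm, volume_mm3.
#' @export
morphologySummary <- function(surfaces, mask) {
  stopifnot(is(surfaces, "CartilageSurfaces"))
  data.frame(mean_thickness_mm = mean(surfaces@thickness),
             sd_thickness_mm = stats::sd(surfaces@thickness),
             volume_mm3 = maskVolume(mask))
}

#' Write a 2D thickness map (PNG) and per-point CSV
#'
#' The CSV (point id, flattened coordinates, thickness) is the quantitative
#' surface of record; the PNG is a qualitative scatter of the flattened
#' subchondral cloud colored by thickness.
#'
#' @param surfaces a [CartilageSurfaces-class].
#' @param csvFile,pngFile output paths (either may be NULL to skip).
#' @return invisibly, the per-point data.frame.
#' @export
writeThicknessMap <- function(surfaces, csvFile = NULL, pngFile = NULL) {
  stopifnot(is(surfaces, "CartilageSurfaces"))
  df <- data.frame(point_id = seq_len(nrow(surfaces@flatCoords)),
                   x_flat = surfaces@flatCoords[, 1],
                   y_flat = surfaces@flatCoords[, 2],
                   thickness_mm = surfaces@thickness)
  if (!is.null(csvFile)) utils::write.csv(df, csvFile, row.names = FALSE)
  if (!is.null(pngFile)) {
    grDevices::png(pngFile, width = 800, height = 600)
    on.exit(grDevices::dev.off())
    pal <- grDevices::hcl.colors(64, "viridis")
    tnorm <- (df$thickness_mm - min(df$thickness_mm)) /
      max(diff(range(df$thickness_mm)), 1e-9)
    graphics::plot(df$x_flat, df$y_flat,
                   col = pal[pmax(1, ceiling(tnorm * 64))], pch = 16,
                   xlab = "arc length (mm)", ylab = "slice position (mm)",
                   main = "Cartilage thickness map")
  }
  invisible(df)
}
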