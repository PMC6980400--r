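# Contours, side separation, flattening, thickness and volume.

test_that("disk contours track the analytic circle at sub-voxel precision", {
  d <- c(1L, 64L, 64L)
  arr <- array(0, d)
  ctr <- c(31.5, 31.5) # 0-based index center
  r <- 20
  for (j in 1:64) for (k in 1:64)
    if ((j - 1 - ctr[1])^2 + (k - 1 - ctr[2])^2 <= r^2) arr[1, j, k] <- 1
  cl <- extractContours(mask_from(arr), sliceAxis = 1L)
  pts <- do.call(rbind, lapply(cl, `[[`, "points"))
  rad <- sqrt((pts[, 2] - ctr[1])^2 + (pts[, 3] - ctr[2])^2)
  expect_lt(max(abs(rad - r)), 0.71)
  # point count ~ perimeter / step
  step <- mean(sqrt(rowSums(diff(pts[, 2:3])^2)))
  expect_lt(abs(nrow(pts) - 2 * pi * r / step) / (2 * pi * r / step), 0.1)
})

test_that("degenerate single-voxel contours do not crash", {
  arr <- array(0, c(3, 9, 9)); arr[2, 5, 5] <- 1
  cl <- extractContours(mask_from(arr))
  expect_length(cl, 1L)
  # its 4 boundary edge midpoints (the polyline may close on itself)
  expect_equal(nrow(unique(round(cl[[1]]$points, 9))), 4L)
  expect_error(extractContours(mask_from(array(0, c(2, 2, 2)))), "empty")
})

test_that("contour points lie on the mask boundary", {
  ph <- makeKneePhantom(phantomSpec(dim = c(8L, 48L, 48L),
                                    spacing = c(2, 1, 1)))
  cl <- extractContours(ph$cartilageMask)
  pts <- do.call(rbind, lapply(cl, `[[`, "points"))
  idx <- physicalToIndex(geometry(ph$cartilageMask), pts)
  bound <- oracle_boundary(voxels(ph$cartilageMask))
  # every sub-voxel contour point sits within one voxel of a boundary voxel
  # center (contour vertices are edge midpoints between boundary voxels and
  # their background neighbours)
  d <- oracle_nn_dists(idx, bound)
  expect_lt(max(d), 1 + 1e-9)
})

test_that("side separation assigns inner points to the subchondral cloud", {
  # full annulus, inner radius 10, outer 12
  d <- c(3L, 64L, 64L)
  arr <- array(0, d)
  ctr <- c(31.5, 31.5)
  for (j in 1:64) for (k in 1:64) {
    rr <- sqrt((j - 1 - ctr[1])^2 + (k - 1 - ctr[2])^2)
    if (rr > 10 && rr <= 12) arr[, j, k] <- 1
  }
  sides <- splitSides(extractContours(mask_from(arr)))
  rs <- sqrt((sides$subchondral[, 2] - ctr[1])^2 +
               (sides$subchondral[, 3] - ctr[2])^2)
  ra <- sqrt((sides$articular[, 2] - ctr[1])^2 +
               (sides$articular[, 3] - ctr[2])^2)
  expect_true(all(rs < 11))
  expect_true(all(ra > 11))
  # partition: no point in both clouds
  key <- function(m) paste(round(m[, 1], 6), round(m[, 2], 6),
                           round(m[, 3], 6))
  expect_length(intersect(key(sides$subchondral), key(sides$articular)), 0L)
})

test_that("a one-voxel-thick shell still yields two nonempty sides", {
  ph <- makeKneePhantom(phantomSpec(dim = c(6L, 64L, 64L),
                                    spacing = c(2, 1, 1), wall = 1.05))
  sides <- splitSides(extractContours(ph$cartilageMask))
  expect_gt(nrow(sides$subchondral), 0)
  expect_gt(nrow(sides$articular), 0)
})

test_that("flattening unrolls a half-cylinder to its arc length", {
  ph <- makeKneePhantom(phantomSpec(dim = c(20L, 120L, 120L),
                                    spacing = c(1, 0.5, 0.5), wall = 2))
  sides <- splitSides(extractContours(ph$cartilageMask))
  fl <- flattenCartilage(sides$subchondral)
  width <- diff(range(fl$flat[, 1]))
  expect_lt(abs(width - pi * fl$radius) / (pi * fl$radius), 0.02)
  # flat y range equals the slice span in mm
  expect_equal(diff(range(fl$flat[, 2])),
               diff(range(sides$subchondral[, 1])))
  # forced theta arithmetic: points on a radius-10 circle, angular
  # separation pi/2 -> flat-x separation theta * r = 15.708 mm
  ang <- c(0, pi / 4, pi / 2)
  circ <- cbind(10 * cos(ang), 10 * sin(ang))
  sub <- rbind(cbind(0, circ), cbind(1, circ))
  fl2 <- flattenCartilage(sub)
  expect_equal(fl2$radius, 10, tolerance = 1e-9)
  expect_equal(as.numeric(abs(fl2$flat[3, 1] - fl2$flat[1, 1])),
               pi / 2 * 10, tolerance = 1e-6)
  expect_error(flattenCartilage(sub[1:3, , drop = FALSE]), "2 slices")
})

test_that("thickness is the 3D nearest-neighbour distance", {
  cloud <- matrix(stats::rnorm(60), 20, 3)
  expect_equal(cartilageThickness(cloud, cloud), rep(0, 20))
  set.seed(37)
  a <- matrix(stats::rnorm(300), 100, 3)
  b <- matrix(stats::rnorm(300), 100, 3)
  expect_equal(cartilageThickness(a, b), oracle_nn_dists(a, b),
               tolerance = 1e-12)
  expect_error(cartilageThickness(a, a[0, , drop = FALSE]), "empty")
})

test_that("one-sided thickness never exceeds the symmetric Hausdorff", {
  set.seed(41)
  for (rep in 1:10) {
    a <- matrix(stats::rnorm(90), 30, 3)
    b <- matrix(stats::rnorm(90), 30, 3)
    one_sided <- max(cartilageThickness(a, b))
    hausdorff <- max(one_sided, max(cartilageThickness(b, a)))
    expect_lte(one_sided, hausdorff)
  }
})

test_that("an analytic 2 mm shell is recovered end to end", {
  ph <- makeKneePhantom(phantomSpec(dim = c(30L, 120L, 120L),
                                    spacing = c(0.5, 0.5, 0.5), wall = 2))
  surf <- morphologyAnalysis(ph$cartilageMask)
  summ <- morphologySummary(surf, ph$cartilageMask)
  expect_lt(abs(summ$mean_thickness_mm - 2), 0.3)
  expect_lt(abs(summ$volume_mm3 - ph$truth$volume) / ph$truth$volume, 0.03)
  # flattened area of the half-cylindrical shell ~ pi * r_mean * length
  fl <- flattenCartilage(surf@subchondral)
  area <- diff(range(fl$flat[, 1])) * diff(range(fl$flat[, 2]))
  expect_lt(abs(area - pi * fl$radius * diff(range(fl$flat[, 2]))) /
              (pi * fl$radius * diff(range(fl$flat[, 2]))), 0.05)
})

test_that("volume is exact arithmetic on voxel counts and spacing", {
  expect_equal(maskVolume(mask_from(array(0, c(4, 4, 4)))), 0)
  arr <- array(0, c(10, 10, 10)); arr[1:1000 <= 1000] <- 1
  m <- BinaryMask(arr, spacing = c(0.3646, 0.3646, 0.7))
  expect_equal(maskVolume(m), 1000 * 0.3646^2 * 0.7)
  m2 <- BinaryMask(arr, spacing = 2 * c(0.3646, 0.3646, 0.7))
  expect_equal(maskVolume(m2), 8 * maskVolume(m))
})

test_that("thickness maps are written as CSV + PNG", {
  ph <- makeKneePhantom(phantomSpec(dim = c(10L, 64L, 64L),
                                    spacing = c(1.5, 1, 1)))
  surf <- morphologyAnalysis(ph$cartilageMask)
  csv <- tempfile(fileext = ".csv"); png <- tempfile(fileext = ".png")
  df <- writeThicknessMap(surf, csv, png)
  expect_true(file.exists(csv) && file.exists(png))
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(surf@subchondral))
  expect_equal(back$thickness_mm, df$thickness_mm)
})
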