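# Registration engine: recovery of known transforms, inversion, mask
# warping, displacement-field algebra.

test_that("registering an image to itself stays at the identity", {
  ph <- small_cohort()[[3]]
  ch <- registerImages(ph$image, ph$image, models = "rigid",
                       control = small_control())
  p <- rbind(c(10, 30, 20), c(20, 40, 10))
  d <- applyTransform(ch, p) - p
  expect_lt(max(abs(d)), 0.5 * min(spacing(ph$image)))
  expect_false(ch@failed)
})

test_that("a known rigid displacement is recovered within half a voxel", {
  # grid long enough that the shifted shell keeps both free ends in view
  base <- phantomSpec(dim = c(28L, 64L, 64L), spacing = c(1, 1, 1),
                      shellLength = 14, noiseSigma = 2, seed = 8)
  ph <- makeKneePhantom(base)
  mvspec <- base; mvspec$seed <- 9L; mvspec$shift <- c(4, -2, 1)
  mv <- makeKneePhantom(mvspec)
  ch <- registerImages(ph$image, mv$image, models = "rigid",
                       control = small_control())
  # content moved by +d, so the fixed->moving map must be x -> x + d
  p <- c(12, 32, 16)
  delta <- as.vector(applyTransform(ch, p)) - p
  expect_lt(max(abs(delta - c(4, -2, 1))), 0.5)
})

test_that("a similarity registration recovers a 10% scale within 2%", {
  ph <- small_cohort()[[3]]
  sc <- makeKneePhantom(phantomSpec(dim = c(20L, 64L, 64L),
                                    spacing = c(1.2, 1, 1), noiseSigma = 2,
                                    seed = 10, boneRadius = 22, wall = 2.2,
                                    shellLength = 0.84 * 22))
  ch <- registerImages(ph$image, sc$image,
                       models = c("rigid", "similarity"),
                       control = small_control())
  A <- matrix(ch@stages[[1]]$A, 3, 3)
  scale <- det(A)^(1 / 3)
  expect_lt(abs(scale - 1.1) / 1.1, 0.02)
})

test_that("closed-form inversion of affine chains is exact", {
  g <- list(dim = c(8L, 8L, 8L), spacing = c(1, 1, 1), origin = c(0, 0, 0),
            direction = diag(3))
  id <- identityChain(g)
  p <- rbind(c(1, 2, 3), c(4, 5, 6))
  expect_equal(applyTransform(invertTransform(id), p), p)
  tr <- cartiflow:::.new_chain(
    list(cartiflow:::.affine_stage(diag(3), c(3, -1, 2))), g, "rigid")
  inv <- invertTransform(tr)
  expect_equal(applyTransform(inv, p), p - rep(c(3, -1, 2), each = 2))
})

test_that("a smooth synthetic B-spline field inverts to sub-voxel residual", {
  set.seed(17)
  g <- list(dim = c(24L, 24L, 24L), spacing = c(1, 1, 1),
            origin = c(0, 0, 0), direction = diag(3))
  gdim <- c(7L, 7L, 7L)
  coef <- array(stats::rnorm(prod(gdim) * 3, 0, 0.8), c(gdim, 3))
  st <- cartiflow:::.bspline_stage(c(-10, -10, -10), c(7, 7, 7), gdim, coef)
  ch <- cartiflow:::.new_chain(list(st), g, "bspline")
  inv <- invertTransform(ch)
  pts <- cartiflow:::.grid_points(g)
  pts <- pts[seq(1, nrow(pts), by = 7), ]
  rt <- applyTransform(inv, applyTransform(ch, pts))
  expect_lt(mean(sqrt(rowSums((rt - pts)^2))), 0.5 * min(g$spacing))
})

test_that("mask warping is nearest-neighbour and count-preserving", {
  arr <- array(0, c(12, 12, 12))
  arr[5:8, 5:8, 5:8] <- 1
  m <- mask_from(arr)
  g <- geometry(m)
  id <- identityChain(g)
  expect_identical(voxels(warpMask(m, id, g)), arr)
  # shift by exactly one voxel: interior mask keeps its foreground count
  sh <- cartiflow:::.new_chain(
    list(cartiflow:::.affine_stage(diag(3), c(1, 0, 0))), g, "rigid")
  w <- warpMask(m, sh, g)
  expect_equal(sum(voxels(w)), sum(arr))
  expect_true(all(voxels(w) %in% c(0, 1)))
})

test_that("warp composed with its inverse preserves a phantom shell", {
  ph <- small_cohort()[[3]]
  mv <- small_cohort()[[4]]
  ch <- registerImages(ph$image, mv$image,
                       models = c("rigid", "similarity", "bspline"),
                       focusMask = ph$femurMask, control = small_control())
  inv <- invertTransform(ch, geometry(mv$image))
  fwd_mask <- warpMask(ph$cartilageMask, inv, geometry(mv$image))
  back <- warpMask(fwd_mask, ch, geometry(ph$image))
  expect_gte(dice(back, ph$cartilageMask), 0.95)
})

test_that("field averaging follows the arithmetic definition", {
  g <- c(6L, 6L, 6L)
  mk <- function(v) displacementField(
    array(rep(v, each = prod(g)), c(g, 3)))
  region <- mask_from(array(1, g))
  f1 <- mk(c(1, 0, 0)); f2 <- mk(c(0, 1, 0)); f3 <- mk(c(0, 0, 1))
  expect_equal(averageFields(list(f1))@field, f1@field)
  neg <- displacementField(-f1@field)
  expect_equal(max(abs(averageFields(list(f1, neg))@field)), 0)
  avg <- averageFields(list(f1, f2, f3), region)
  expect_equal(unique(as.vector(avg@field)), 1 / 3)
  expect_error(averageFields(list()), "empty")
})

test_that("field distance matches the brute-force loop and is a metric", {
  set.seed(19)
  g <- c(5L, 5L, 4L)
  region <- mask_from(random_mask_array(g, 0.5))
  rf <- function() displacementField(array(stats::rnorm(prod(g) * 3),
                                           c(g, 3)))
  f <- rf(); h <- rf(); k <- rf()
  expect_equal(fieldDistance(f, f, region), 0)
  # constant difference (3, 4, 0) -> 5
  g345 <- displacementField(f@field + rep(c(3, 4, 0), each = prod(g)))
  expect_equal(fieldDistance(f, g345, region), 5)
  # brute-force accumulation
  sel <- which(voxels(region) > 0, arr.ind = TRUE)
  acc <- 0
  for (r in seq_len(nrow(sel))) {
    d <- f@field[sel[r, 1], sel[r, 2], sel[r, 3], ] -
      h@field[sel[r, 1], sel[r, 2], sel[r, 3], ]
    acc <- acc + sqrt(sum(d^2))
  }
  expect_equal(fieldDistance(f, h, region), acc / nrow(sel))
  # metric properties
  expect_equal(fieldDistance(f, h, region), fieldDistance(h, f, region))
  expect_lte(fieldDistance(f, k, region),
             fieldDistance(f, h, region) + fieldDistance(h, k, region))
})

test_that("registration with a fixed seed is bit-reproducible", {
  ph <- small_cohort()[[3]]
  mv <- small_cohort()[[2]]
  ch1 <- registerImages(ph$image, mv$image, models = "rigid",
                        control = small_control(seed = 5))
  ch2 <- registerImages(ph$image, mv$image, models = "rigid",
                        control = small_control(seed = 5))
  expect_identical(ch1@stages, ch2@stages)
})
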