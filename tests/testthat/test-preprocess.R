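# Spatial and intensity standardization.

test_that("orientToRAI is the identity on RAI images and idempotent", {
  img <- img_from(array(stats::rnorm(24), c(2, 3, 4)))
  expect_identical(voxels(orientToRAI(img)), voxels(img))
  flipped <- img
  flipped@direction <- diag(c(-1, 1, 1))
  once <- orientToRAI(flipped)
  expect_identical(voxels(orientToRAI(once)), voxels(once))
  expect_lt(max(abs(direction(once) - diag(3))), 1e-12)
})

test_that("reorientation preserves the physical position of every landmark", {
  set.seed(11)
  for (rep in 1:20) {
    P <- random_signed_permutation()
    arr <- array(0, c(4, 5, 6))
    marks <- rbind(c(0, 0, 0), c(3, 1, 2), c(2, 4, 5))
    for (r in seq_len(nrow(marks)))
      arr[marks[r, 1] + 1, marks[r, 2] + 1, marks[r, 3] + 1] <- r * 10
    img <- Image3D(arr, spacing = stats::runif(3, 0.5, 2),
                   origin = stats::rnorm(3), direction = P)
    out <- orientToRAI(img)
    expect_lt(max(abs(direction(out) - diag(3))), 1e-12)
    for (r in seq_len(nrow(marks))) {
      p_old <- indexToPhysical(img, marks[r, , drop = FALSE])
      idx_new <- which(voxels(out) == r * 10, arr.ind = TRUE) - 1
      p_new <- indexToPhysical(out, idx_new)
      expect_lt(max(abs(p_new - p_old)), 1e-9)
    }
  }
})

test_that("laterality flip mirrors content along x and is an involution", {
  arr <- array(0, c(5, 3, 3))
  arr[1, 2, 2] <- 7 # marker at the left edge
  img <- img_from(arr)
  expect_identical(voxels(flipLaterality(img, "left")), arr)
  r <- flipLaterality(img, "right")
  expect_equal(which(voxels(r) == 7, arr.ind = TRUE)[1], 5) # nx - 1 - i
  expect_identical(voxels(flipLaterality(r, "right")), arr)
  expect_error(flipLaterality(img, "up"), "laterality")
})

test_that("resetOrigin zeroes the origin and nothing else", {
  img <- img_from(array(1:8, c(2, 2, 2)), origin = c(5, -3, 2))
  out <- resetOrigin(img)
  expect_equal(origin(out), c(0, 0, 0))
  expect_identical(voxels(out), voxels(img))
  expect_equal(as.vector(indexToPhysical(out, c(0, 0, 0))), c(0, 0, 0))
  expect_identical(voxels(resetOrigin(out)), voxels(out))
})

test_that("spatial standardization composite is idempotent", {
  set.seed(3)
  img <- Image3D(array(stats::rnorm(60), c(3, 4, 5)),
                 origin = c(4, 5, 6), direction = random_signed_permutation())
  once <- standardizeSpace(img, "right")
  twice <- standardizeSpace(once, "left") # already left-lateral after flip
  expect_identical(voxels(twice), voxels(once))
  expect_equal(origin(twice), origin(once))
})

test_that("bias correction leaves an unbiased phantom alone and fixes gain", {
  # constant-tissue phantom: a uniform-intensity ball in background
  d <- c(32L, 32L, 16L)
  arr <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1]))
    if ((i - 16)^2 + (j - 16)^2 + ((k - 8) * 2)^2 <= 12^2)
      arr[i, j, k] <- 50
  ball <- img_from(arr)
  out <- correctFieldInhomogeneity(ball)
  rel <- abs(voxels(out) - arr) / pmax(arr, 1e-9)
  expect_lt(max(rel[arr > 0]), 0.02)

  # same phantom under a smooth multiplicative gain in [0.8, 1.2]
  gx <- seq(0.8, 1.2, length.out = d[1])
  gz <- seq(0.9, 1.1, length.out = d[3])
  gain <- gx %o% rep(1, d[2]) %o% gz
  biased <- img_from(arr * gain)
  corr <- correctFieldInhomogeneity(biased)
  tissue <- arr > 0
  cv <- function(v) stats::sd(v) / mean(v)
  expect_lt(cv(voxels(corr)[tissue]), cv(voxels(biased)[tissue]))
  expect_true(all(voxels(corr) >= 0))
  m0 <- mean(voxels(biased)[tissue]); m1 <- mean(voxels(corr)[tissue])
  expect_lt(abs(m1 - m0) / m0, 0.1)
  expect_error(correctFieldInhomogeneity(img_from(array(0, c(3, 3, 3)))),
               "all-zero")
})

test_that("intensity rescaling maps the robust range onto the target", {
  arr <- array(stats::runif(60, 10, 20), c(3, 4, 5))
  arr[1] <- 10; arr[2] <- 20
  out <- rescaleIntensity(img_from(arr), c(0, 100))
  expect_equal(min(voxels(out)), 0)
  expect_equal(max(voxels(out)), 100)
  # forced affine map: 15 from [10, 20] -> 50
  arr2 <- array(c(10, 15, 20, 12), c(4, 1, 1))
  out2 <- rescaleIntensity(img_from(arr2), c(0, 100))
  expect_equal(voxels(out2)[2], 50)
  expect_error(rescaleIntensity(img_from(array(5, c(2, 2, 2)))), "constant")
})

test_that("curvature-flow smoothing denoises without moving the edge", {
  set.seed(21)
  arr <- array(0, c(24, 24, 8))
  arr[1:12, , ] <- 100 # step edge between x index 12 and 13
  noisy <- arr + array(stats::rnorm(length(arr), 0, 5), dim(arr))
  img <- img_from(noisy)
  expect_identical(voxels(smoothEdges(img, 0)), voxels(img))
  const <- img_from(array(42, c(6, 6, 6)))
  expect_equal(voxels(smoothEdges(const, 5)), voxels(const))
  sm <- smoothEdges(img, 5)
  # in-region variance strictly decreases
  expect_lt(stats::var(as.vector(voxels(sm)[3:10, , ])),
            stats::var(as.vector(voxels(img)[3:10, , ])))
  # the 50%-level crossing stays within one voxel
  prof <- rowMeans(voxels(sm)[, , 4])
  cross <- which(prof < 50)[1]
  expect_true(cross %in% 12:14)
  # no new extrema
  expect_gte(min(voxels(sm)), min(noisy) - 1e-6)
  expect_lte(max(voxels(sm)), max(noisy) + 1e-6)
  expect_error(smoothEdges(img, 5, timestep = 0.2), "stability")
})

test_that("intensity operations never touch the geometry", {
  ph <- makeKneePhantom(phantomSpec(dim = c(8L, 32L, 32L),
                                    spacing = c(2, 1.5, 1.5),
                                    noiseSigma = 1))
  img <- ph$image
  img@origin <- c(3, 4, 5)
  for (op in list(function(x) correctFieldInhomogeneity(x),
                  function(x) rescaleIntensity(x),
                  function(x) smoothEdges(x, 2))) {
    out <- op(img)
    expect_identical(spacing(out), spacing(img))
    expect_identical(origin(out), origin(img))
    expect_identical(direction(out), direction(img))
  }
})

test_that("preprocessImage applies the fixed intensity order", {
  ph <- makeKneePhantom(phantomSpec(dim = c(8L, 32L, 32L),
                                    spacing = c(2, 1.5, 1.5),
                                    noiseSigma = 1))
  out <- preprocessImage(ph$image, "left")
  expect_equal(attr(out, "steps"),
               c("orientToRAI", "flipLaterality", "resetOrigin",
                 "correctFieldInhomogeneity", "rescaleIntensity",
                 "smoothEdges"))
  expect_gte(min(voxels(out)), 0)
  expect_lte(max(voxels(out)), 100)
})
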