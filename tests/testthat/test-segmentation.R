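# Quality metrics, batch evaluation, mode stage lists and reference search
# contracts (the cohort-scale behaviour lives in test-acceptance.R).

test_that("dice follows its closed-form cases", {
  a <- array(0, c(10, 10, 10)); a[1:5, , 1] <- 1
  m <- mask_from(a)
  expect_equal(dice(m, m), 1)
  b <- array(0, c(10, 10, 10)); b[6:10, , 2] <- 1
  expect_equal(dice(m, mask_from(b)), 0)
  # |NM| = 100, |GT| = 50, overlap 50
  nm <- array(0, c(10, 10, 10)); nm[1:100] <- 1
  gt <- array(0, c(10, 10, 10)); gt[51:100] <- 1
  expect_equal(dice(mask_from(nm), mask_from(gt)), 2 * 50 / 150)
  expect_error(dice(mask_from(array(0, c(2, 2, 2))),
                    mask_from(array(0, c(2, 2, 2)))), "empty")
  expect_error(dice(m, mask_from(a, spacing = c(2, 1, 1))), "geometry")
})

test_that("dice is symmetric and monotone in the overlap", {
  set.seed(23)
  for (rep in 1:20) {
    a <- mask_from(random_mask_array())
    b <- mask_from(random_mask_array())
    expect_equal(dice(a, b), dice(b, a))
    expect_equal(dice(a, b), oracle_dice(voxels(a), voxels(b)))
  }
  # growing the overlap while holding |NM|, |GT| fixed never lowers DSC
  nm <- array(0, c(6, 6, 1)); nm[1:6, 1, 1] <- 1
  gt <- array(0, c(6, 6, 1)); gt[1:6, 2, 1] <- 1
  prev <- dice(mask_from(nm), mask_from(gt))
  for (k in 1:5) {
    gt[k, 2, 1] <- 0; gt[k, 1, 1] <- 1 # move one voxel into the overlap
    cur <- dice(mask_from(nm), mask_from(gt))
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("average surface distance follows the definition", {
  a <- array(0, c(10, 10, 10)); a[3:6, 3:6, 3:6] <- 1
  m <- mask_from(a)
  expect_equal(averageSurfaceDistance(m, m), 0)
  # two parallel one-voxel plates 3 mm apart
  p1 <- array(0, c(10, 10, 1)); p1[2, 1:10, 1] <- 1
  p2 <- array(0, c(10, 10, 1)); p2[5, 1:10, 1] <- 1
  expect_equal(averageSurfaceDistance(mask_from(p1), mask_from(p2)), 3)
  expect_error(averageSurfaceDistance(m, mask_from(array(0, dim(a)))),
               "nonempty")
})

test_that("ASD matches the brute-force oracle and scales with spacing", {
  set.seed(29)
  for (rep in 1:10) {
    a <- mask_from(random_mask_array(c(7L, 7L, 7L)))
    b <- mask_from(random_mask_array(c(7L, 7L, 7L)))
    expect_equal(averageSurfaceDistance(a, b), oracle_asd(a, b),
                 tolerance = 1e-12)
    expect_equal(averageSurfaceDistance(a, b),
                 averageSurfaceDistance(b, a))
    a2 <- mask_from(voxels(a), spacing = c(2, 2, 2))
    b2 <- mask_from(voxels(b), spacing = c(2, 2, 2))
    expect_equal(averageSurfaceDistance(a2, b2),
                 2 * averageSurfaceDistance(a, b), tolerance = 1e-9)
  }
})

test_that("evaluateBatch isolates failures and aggregates consistently", {
  a <- array(0, c(8, 8, 8)); a[3:5, 3:5, 3:5] <- 1
  m <- mask_from(a)
  pairs <- rep(list(list(nm = m, gt = m)), 4)
  pairs[[5]] <- list(nm = m, gt = mask_from(array(0, c(8, 8, 8))), id = "bad")
  f <- tempfile(fileext = ".csv")
  df <- evaluateBatch(pairs, file = f)
  expect_equal(nrow(df), 5)
  expect_equal(sum(df$failed), 1)
  expect_true(df$failed[df$image_id == "bad"])
  summ <- attr(df, "summary")
  expect_equal(summ$dsc[summ$image_id == "mean"], 1)
  expect_equal(summ$dsc[summ$image_id == "sd"], 0)
  # batch stats equal recomputation from the emitted CSV
  back <- utils::read.csv(f)
  valid <- back[!(back$image_id %in% c("mean", "sd")) &
                  back$failed %in% "FALSE", ]
  expect_equal(mean(valid$dsc), summ$dsc[summ$image_id == "mean"])
})

test_that("segmentation modes apply exactly the documented stage lists", {
  co <- small_cohort()
  ref <- co[[3]]
  ctl <- small_control()
  seg_long <- segmentCartilage(ref$image, ref$cartilageMask, co[[4]]$image,
                               "longitudinal", referenceFemur = ref$femurMask,
                               control = ctl)
  expect_equal(seg_long$stagesApplied, c("rigid", "bspline"))
  expect_length(seg_long$stagesApplied, 2L)
  ctl_mm <- small_control(); ctl_mm$metric <- "mi"
  seg_mm <- segmentCartilage(ref$image, ref$cartilageMask, co[[4]]$image,
                             "multimodal", referenceFemur = ref$femurMask,
                             control = ctl_mm)
  expect_equal(seg_mm$stagesApplied, "rigid")
  expect_length(seg_mm$chain@stages, 1L)
  expect_error(cartiflow:::.mode_models("fancy"), "unknown")
})

test_that("segmenting the reference against itself is near-perfect", {
  co <- small_cohort()
  ref <- co[[3]]
  seg <- segmentCartilage(ref$image, ref$cartilageMask, ref$image,
                          "intersubject", referenceFemur = ref$femurMask,
                          control = small_control())
  expect_gte(dice(seg$mask, ref$cartilageMask), 0.99)
  expect_false(seg$failed)
})

test_that("a rigidly displaced phantom segments well in multimodal mode", {
  co <- small_cohort()
  ref <- co[[3]]
  # displacement chosen as a whole number of voxels so the voxelized
  # ground-truth shell is an exact translate of the reference shell and the
  # check isolates rigid-registration accuracy from re-voxelization effects
  disp <- makeKneePhantom(phantomSpec(dim = c(20L, 64L, 64L),
                                      spacing = c(1.2, 1, 1),
                                      noiseSigma = 2, seed = 31,
                                      shift = c(2.4, -3, 2)))
  ctl <- small_control(); ctl$metric <- "mi"
  seg <- segmentCartilage(ref$image, ref$cartilageMask, disp$image,
                          "multimodal", referenceFemur = ref$femurMask,
                          control = ctl)
  expect_gte(dice(seg$mask, disp$cartilageMask), 0.95)
})

test_that("findReference handles the trivial datasets by contract", {
  co <- small_cohort()
  one <- findReference(list(co[[1]]$image), list(co[[1]]$femurMask))
  expect_equal(one$referenceIndex, 1L)
  expect_true(one$converged)
  expect_equal(max(one$state$iteration), 1L)
  expect_error(findReference(list(), list()), "empty")
  expect_error(findReference(list(co[[1]]$image), list(NULL)), "femur mask")
})

test_that("identical images tie-break to the lowest index and converge", {
  ph <- makeKneePhantom(phantomSpec(dim = c(10L, 40L, 40L),
                                    spacing = c(2, 1.5, 1.5)))
  imgs <- list(ph$image, ph$image, ph$image)
  msks <- list(ph$femurMask, ph$femurMask, ph$femurMask)
  ctl <- regControl(samples = 600L, bsplineIterations = c(30L, 20L),
                    seed = 2L)
  fr <- findReference(imgs, msks, seedIndex = 2L, control = ctl)
  expect_equal(fr$referenceIndex, 1L)
  expect_true(fr$converged)
  expect_equal(max(fr$state$iteration), 2L)
})
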