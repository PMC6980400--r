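# Image containers, geometry mapping, MetaImage/DICOM I/O, image lists.

test_that("Image3D validity enforces the geometry invariants", {
  expect_error(Image3D(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "spacing")
  expect_error(Image3D(array(0, c(2, 2, 2)),
                       direction = matrix(1, 3, 3)), "orthonormal")
  expect_error(BinaryMask(array(0.5, c(2, 2, 2))), "0 or 1")
  expect_s4_class(BinaryMask(array(0, c(2, 2, 2))), "BinaryMask")
})

test_that("index<->physical mapping is a bijection on the grid", {
  set.seed(42)
  for (rep in 1:10) {
    img <- Image3D(array(0, c(4, 5, 6)),
                   spacing = stats::runif(3, 0.2, 3),
                   origin = stats::rnorm(3, 0, 10),
                   direction = random_rotation())
    idx <- as.matrix(expand.grid(0:3, 0:4, 0:5))
    dimnames(idx) <- NULL
    p <- indexToPhysical(img, idx)
    back <- physicalToIndex(img, p)
    expect_lt(max(abs(back - idx)), 1e-9)
  }
})

test_that("MetaImage round trip preserves voxels exactly and geometry", {
  set.seed(7)
  img <- Image3D(array(stats::rnorm(60), c(3, 4, 5)),
                 spacing = c(0.3646, 0.3646, 0.7), origin = c(1, -2, 3))
  f <- tempfile(fileext = ".mha")
  writeImage(img, f)
  back <- readImage(f)
  expect_identical(voxels(back), voxels(img))
  expect_lt(max(abs(spacing(back) - spacing(img))), 1e-12)
  expect_lt(max(abs(origin(back) - origin(img))), 1e-12)
  expect_lt(max(abs(direction(back) - direction(img))), 1e-12)
})

test_that("masks are written as 8-bit and preserve foreground counts", {
  arr <- array(0, c(10, 10, 10))
  arr[sample(1000, 7)] <- 1
  m <- mask_from(arr)
  f <- tempfile(fileext = ".mha")
  writeImage(m, f)
  back <- readImage(f)
  expect_equal(sum(voxels(back)), 7)
  expect_true(all(voxels(back) %in% c(0, 1)))
  # empty mask round trip
  f2 <- tempfile(fileext = ".mha")
  writeImage(mask_from(array(0, c(3, 3, 3))), f2)
  expect_equal(sum(voxels(readImage(f2))), 0)
})

test_that("writing non-finite voxels is rejected", {
  arr <- array(1, c(2, 2, 2)); arr[1] <- NaN
  expect_error(writeImage(Image3D(arr), tempfile(fileext = ".mha")),
               "non-finite")
})

test_that("DICOM series are assembled by spatial position, not filename", {
  set.seed(3)
  vol <- array(sample(0:4000, 8 * 6 * 5, replace = TRUE), c(8, 6, 5))
  d1 <- file.path(tempfile(), "sorted")
  d2 <- file.path(tempfile(), "shuffled")
  write_dicom_volume(d1, vol, spacing = c(0.3646, 0.3646, 0.7),
                     origin = c(10, -5, 2))
  write_dicom_volume(d2, vol, spacing = c(0.3646, 0.3646, 0.7),
                     origin = c(10, -5, 2), shuffle = TRUE)
  a <- readImage(d1); b <- readImage(d2)
  expect_identical(voxels(a), voxels(b))
  expect_equal(voxels(a), vol, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(spacing(a), c(0.3646, 0.3646, 0.7), tolerance = 1e-9)
  expect_equal(origin(a), c(10, -5, 2), tolerance = 1e-9)
})

test_that("inconsistent DICOM slice spacing is rejected with slice names", {
  vol <- array(1, c(4, 4, 3))
  d <- tempfile()
  dir.create(d)
  for (k in 1:3)
    write_dicom_slice(file.path(d, sprintf("s%d.dcm", k)),
                      matrix(1L, 4, 4),
                      ipp = c(0, 0, c(0, 1, 2.5)[k])) # spacings 1 and 1.5
  expect_error(readImage(d), "inconsistent")
})

test_that("multi-echo DICOM series split into ascending-time volumes", {
  set.seed(5)
  d <- tempfile()
  v1 <- array(100L, c(4, 4, 3)); v2 <- array(50L, c(4, 4, 3))
  # write the long echo first: ordering must come from metadata
  write_dicom_volume(d, v2, echoTime = 30, prefix = "e2_")
  write_dicom_volume(d, v1, echoTime = 10, prefix = "e1_")
  vols <- readDicomSeries(d)
  expect_length(vols, 2L)
  expect_equal(attr(vols, "times"), c(10, 30))
  expect_equal(voxels(vols[[1]])[1], 100)
  expect_equal(voxels(vols[[2]])[1], 50)
  expect_error(readImage(d), "readDicomSeries")
})

test_that("image lists parse with comments, defaults and order", {
  d <- tempfile(); dir.create(d)
  for (f in c("a.mha", "b.mha", "c.mha"))
    writeImage(img_from(array(1, c(2, 2, 2))), file.path(d, f))
  lst <- file.path(d, "list.txt")
  writeLines(c("# cohort", "", "a.mha - - left moving",
               "b.mha - - right reference", "c.mha"), lst)
  il <- parseImageList(lst)
  expect_equal(length(il), 3L)
  recs <- imageRecords(il)
  expect_equal(basename(recs$image_path), c("a.mha", "b.mha", "c.mha"))
  expect_equal(recs$laterality, c("left", "right", "left"))
  expect_equal(recs$role, c("moving", "reference", "moving"))
})

test_that("image list errors carry line numbers and token names", {
  d <- tempfile(); dir.create(d)
  writeImage(img_from(array(1, c(2, 2, 2))), file.path(d, "a.mha"))
  lst <- file.path(d, "list.txt")
  writeLines(c("a.mha", "a.mha", "a.mha", "a.mha - - sideways"), lst)
  expect_error(parseImageList(lst), "line 4")
  writeLines("# only comments", lst)
  expect_equal(length(parseImageList(lst)), 0L)
  writeLines("missing.mha", lst)
  expect_error(parseImageList(lst), "does not exist")
  expect_equal(length(parseImageList(lst, checkExists = FALSE)), 1L)
})
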