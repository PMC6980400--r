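# Mono-exponential / log-linear fitting, DESS T2, map statistics and
# series alignment.

test_that("noiseless decay is recovered exactly by both fitters", {
  d <- makeDecaySeries(tb = 40, k = 100, times = c(1, 10, 30, 60))
  fe <- fitExponential(d$series)
  expect_lt(max(abs(voxels(fe@tbMap) - 40) / 40, na.rm = TRUE), 1e-6)
  expect_lt(max(abs(voxels(fe@kMap) - 100) / 100, na.rm = TRUE), 1e-6)
  fl <- fitLinear(d$series)
  expect_lt(max(abs(voxels(fl@tbMap) - voxels(fe@tbMap)), na.rm = TRUE),
            1e-9)
})

test_that("all-zero voxels are invalid, not fitted", {
  g <- list(dim = c(4L, 4L, 1L), spacing = c(1, 1, 1), origin = c(0, 0, 0),
            direction = diag(3))
  d <- makeDecaySeries(tb = 40, k = 100, geom = g)
  for (i in seq_along(d$series@volumes))
    d$series@volumes[[i]]@voxels[1, 1, 1] <- 0
  fe <- fitExponential(d$series)
  expect_equal(voxels(fe@validMask)[1, 1, 1], 0)
  expect_true(is.na(voxels(fe@tbMap)[1, 1, 1]))
})

test_that("two time points are interpolated exactly by the linear fit", {
  d <- makeDecaySeries(tb = 55, k = 80, times = c(5, 25))
  fl <- fitLinear(d$series)
  expect_lt(max(abs(voxels(fl@tbMap) - 55), na.rm = TRUE), 1e-9)
})

test_that("under noise the log-linear fit is the more biased one", {
  biases <- vapply(c(20, 40, 60, 80), function(tb) {
    g <- list(dim = c(25L, 20L, 1L), spacing = c(1, 1, 1),
              origin = c(0, 0, 0), direction = diag(3))
    d <- makeDecaySeries(tb = tb, k = 100, sigma = 1, seed = 100 + tb,
                         geom = g)
    fe <- fitExponential(d$series)
    fl <- fitLinear(d$series)
    c(exp = abs(mean(voxels(fe@tbMap)[voxels(fe@validMask) > 0]) - tb) / tb,
      lin = abs(mean(voxels(fl@tbMap)[voxels(fl@validMask) > 0]) - tb) / tb)
  }, numeric(2))
  expect_lt(max(biases["exp", ]), 0.01)
  expect_gte(mean(biases["lin", ]), mean(biases["exp", ]))
})

test_that("fits are scale-equivariant and time-unit consistent", {
  d <- makeDecaySeries(tb = 40, k = 100, sigma = 0.5, seed = 3)
  f1 <- fitExponential(d$series)
  scaled <- decaySeries(lapply(d$series@volumes, function(v) {
    v@voxels <- v@voxels * 3; v
  }), d$series@times, d$series@kind)
  f2 <- fitExponential(scaled)
  expect_equal(voxels(f2@tbMap), voxels(f1@tbMap), tolerance = 1e-6)
  expect_equal(voxels(f2@kMap), 3 * voxels(f1@kMap), tolerance = 1e-6)
  # seconds instead of milliseconds: Tb scales by 1/1000
  insec <- decaySeries(d$series@volumes, d$series@times / 1000,
                       d$series@kind)
  f3 <- fitLinear(insec, bounds = c(0, 0.2))
  f1l <- fitLinear(d$series)
  expect_equal(voxels(f3@tbMap) * 1000, voxels(f1l@tbMap),
               tolerance = 1e-9)
})

test_that("out-of-bound relaxation times are invalidated, not clamped", {
  d <- makeDecaySeries(tb = 300, k = 100) # above the default 200 ms bound
  expect_error(fitExponential(d$series), "all voxels")
  fe <- fitExponential(d$series, bounds = c(0, 500))
  expect_lt(max(abs(voxels(fe@tbMap) - 300) / 300, na.rm = TRUE), 1e-6)
})

test_that("DESS inversion is the exact inverse of the forward model", {
  prm <- dessParams(16.32, 4.7, 25)
  de <- makeDessPair(t2 = 40, params = prm)
  fit <- t2FromDess(de$echo1, de$echo2, prm)
  expect_lt(max(abs(voxels(fit@tbMap) - 40) / 40, na.rm = TRUE), 1e-6)
  # monotone: larger ratio -> larger T2 (sweep over the valid domain)
  k <- sin(25 * pi / 180 / 2)^2
  ratios <- seq(0.05, 0.95, by = 0.05) * k
  t2s <- -2 * (prm$tr - prm$te) / log(ratios / k)
  expect_true(all(diff(t2s) > 0))
  t2grid <- seq(20, 80, by = 10)
  expect_true(all(diff(dessRatio(t2grid, prm)) > 0))
})

test_that("DESS contract cases: zero echo invalid, unphysical input errors", {
  prm <- dessParams(16.32, 4.7, 25)
  de <- makeDessPair(t2 = 40, params = prm)
  de$echo2@voxels[1, 1, 1] <- 0
  fit <- t2FromDess(de$echo1, de$echo2, prm)
  expect_equal(voxels(fit@validMask)[1, 1, 1], 0)
  bad2 <- de$echo1 # ratio 1 everywhere
  expect_error(t2FromDess(de$echo1, bad2, prm), "unphysical")
  expect_error(dessParams(16.32, 4.7, 0), "flip")
})

test_that("map statistics use the population SD and re-aggregate", {
  g <- list(dim = c(4L, 4L, 2L), spacing = c(1, 1, 1), origin = c(0, 0, 0),
            direction = diag(3))
  tb <- array(40, g$dim)
  d <- makeDecaySeries(tb = tb, k = 100, geom = g)
  fit <- fitLinear(d$series)
  allm <- mask_from(array(1, g$dim))
  st <- mapStatistics(fit, allm)
  expect_equal(st$mean_ms, 40)
  expect_equal(st$sd_ms, 0)
  expect_equal(st$n_voxels, 32)
  # half 30 / half 50 -> mean 40, population SD 10
  tb2 <- array(c(rep(30, 16), rep(50, 16)), g$dim)
  d2 <- makeDecaySeries(tb = tb2, k = 100, geom = g)
  st2 <- mapStatistics(fitLinear(d2$series), allm)
  expect_equal(st2$mean_ms, 40)
  expect_equal(st2$sd_ms, 10)
  # stats equal recomputation from the exported per-voxel values
  fit2 <- fitLinear(d2$series)
  v <- voxels(fit2@tbMap)[voxels(fit2@validMask) > 0]
  expect_equal(st2$mean_ms, mean(v))
})

test_that("series alignment fixes a known shift and keeps times", {
  base <- makeKneePhantom(phantomSpec(dim = c(16L, 48L, 48L),
                                      spacing = c(1.5, 1.2, 1.2),
                                      noiseSigma = 1, seed = 7))
  shif <- makeKneePhantom(phantomSpec(dim = c(16L, 48L, 48L),
                                      spacing = c(1.5, 1.2, 1.2),
                                      noiseSigma = 1, seed = 8,
                                      shift = c(0, 3, 0)))
  tb <- 40; times <- c(1, 10, 30, 60)
  mk <- function(img, t) Image3D(voxels(img) * exp(-t / tb), spacing(img),
                                 origin(img), direction(img))
  ser <- decaySeries(list(mk(shif$image, 1), mk(base$image, 10),
                          mk(base$image, 30), mk(base$image, 60)),
                     times, "T1rho")
  al <- alignSeries(ser, control = regControl(metric = "ncc", levels = 2L,
                                              samples = 1500L))
  expect_identical(al@times, ser@times)
  # measure the residual shift by registering the aligned volume back
  ch <- registerImages(mk(base$image, 1), al@volumes[[1]], models = "rigid",
                       control = regControl(metric = "ncc", levels = 2L))
  p <- c(12, 28, 14)
  expect_lt(max(abs(applyTransform(ch, p) - p)), 0.5)
  # an already-aligned series barely moves
  ser0 <- decaySeries(lapply(times, function(t) mk(base$image, t)), times,
                      "T1rho")
  al0 <- alignSeries(ser0, control = regControl(metric = "ncc",
                                                levels = 2L))
  expect_lt(mean(abs(voxels(al0@volumes[[1]]) - voxels(ser0@volumes[[1]]))),
            0.5 * mean(abs(voxels(ser0@volumes[[1]]))))
})
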