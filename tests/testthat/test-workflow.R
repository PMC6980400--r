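# Workflow driver: stage outputs, manifests, failure isolation, and the
# dependency report (pipeline-level determinism lives in test-acceptance.R).

test_that("make-fixtures + preprocess produce outputs and manifests", {
  od <- tempfile("wf")
  fx <- runStage(runConfig("make-fixtures", outDir = file.path(od, "fix"),
                           seed = 2,
                           params = list(dim = c(10L, 40L, 40L),
                                         spacing = c(2, 1.5, 1.5))))
  lst <- file.path(od, "fix", "imagelist.txt")
  expect_true(file.exists(lst))
  expect_true(file.exists(file.path(od, "fix", "truth.csv")))
  il <- parseImageList(lst)
  expect_equal(length(il), 5L)
  pr <- runStage(runConfig("preprocess", il,
                           outDir = file.path(od, "prep"), seed = 2))
  expect_equal(pr$manifest$status, rep("ok", 5))
  expect_true(all(file.exists(pr$manifest$outputs)))
  expect_true(file.exists(pr$files$manifest))
  log <- readLines(pr$files$log)
  expect_true(any(grepl("pipeline_order: bias>rescale>smooth", log)))
  expect_true(any(grepl("dependencies:", log)))
})

test_that("per-image failures are isolated and the batch continues", {
  od <- tempfile("wf")
  dir.create(od, recursive = TRUE)
  good <- file.path(od, "good.mha")
  writeImage(makeKneePhantom(phantomSpec(dim = c(6L, 24L, 24L),
                                         spacing = c(2, 2, 2)))$image, good)
  bad <- file.path(od, "bad.mha")
  writeLines("not an image", bad)
  il <- imageList(c(good, bad))
  pr <- runStage(runConfig("preprocess", il,
                           outDir = file.path(od, "out")))
  expect_equal(pr$manifest$status, c("ok", "failed"))
  expect_true(nzchar(pr$manifest$message[2]))
})

test_that("the dependency report parses as key:version pairs", {
  dep <- reportDependencies()
  expect_gt(length(dep), 3)
  expect_true(all(nzchar(names(dep))))
  block <- paste(names(dep), dep, sep = ": ")
  parsed <- do.call(rbind, strsplit(block, ": ", fixed = TRUE))
  expect_equal(parsed[, 1], names(dep))
  expect_identical(reportDependencies()[["r_version"]],
                   dep[["r_version"]])
})

test_that("relaxometry stages run from directories of volumes", {
  od <- tempfile("wf"); dir.create(od, recursive = TRUE)
  sd <- file.path(od, "series"); dir.create(sd)
  g <- list(dim = c(8L, 8L, 2L), spacing = c(1, 1, 3),
            origin = c(0, 0, 0), direction = diag(3))
  d <- makeDecaySeries(tb = 40, k = 100, times = c(1, 10, 30, 60),
                       geom = g)
  for (i in seq_along(d$series@times))
    writeImage(d$series@volumes[[i]],
               file.path(sd, sprintf("vol_%02d.mha", d$series@times[i])))
  res <- runStage(runConfig("relaxometry-fit", imageList(sd),
                            outDir = file.path(od, "fit"),
                            params = list(kind = "T1rho",
                                          method = "exponential")))
  expect_equal(res$summary$mean_ms, 40, tolerance = 1e-6)
  expect_true(file.exists(res$summary$image_id[1] |>
                            (\(x) file.path(od, "fit",
                                            paste0(x, "_map.mha")))()))
  # DESS stage
  dd <- file.path(od, "dess"); dir.create(dd)
  prm <- dessParams(16.32, 4.7, 25)
  pair <- makeDessPair(t2 = 40, params = prm, geom = g)
  writeImage(pair$echo1, file.path(dd, "echo1.mha"))
  writeImage(pair$echo2, file.path(dd, "echo2.mha"))
  res2 <- runStage(runConfig("relaxometry-dess", imageList(dd),
                             outDir = file.path(od, "dessout"),
                             params = list(tr = 16.32, te = 4.7,
                                           flip = 25)))
  expect_equal(res2$summary$mean_ms, 40, tolerance = 1e-6)
})

test_that("evaluate stage writes quality rows for mask pairs", {
  od <- tempfile("wf"); dir.create(od, recursive = TRUE)
  ph <- makeKneePhantom(phantomSpec(dim = c(6L, 32L, 32L),
                                    spacing = c(2, 1.5, 1.5)))
  nm <- file.path(od, "nm.mha"); gt <- file.path(od, "gt.mha")
  writeImage(ph$cartilageMask, nm)
  writeImage(ph$cartilageMask, gt)
  il <- imageList(nm, cartilage_mask_path = gt)
  res <- runStage(runConfig("evaluate", il, outDir = file.path(od, "ev")))
  q <- utils::read.csv(file.path(od, "ev", "quality.csv"))
  expect_equal(q$dsc[1], 1)
  expect_equal(q$asd[1], 0)
})

test_that("stage and config validation reject bad inputs", {
  expect_error(runConfig("polish"), "arg")
  cfg <- runConfig("preprocess", imageList(character(0)))
  expect_error(runStage(cfg), "empty")
})
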