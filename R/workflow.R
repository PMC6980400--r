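# Batch workflow driver: stage dispatch over an image list with per-image
# parallelism, per-image failure isolation, seeded determinism and run
# manifests echoing the resolved configuration plus dependency versions.

#' Runtime dependency report
#'
#' Key:version pairs describing the runtime (R version, platform, OS, core
#' package versions), recorded in every run manifest so a run can be
#' reproduced in the same computational environment.
#'
#' @return named character vector; `paste(names(x), x, sep=": ")` yields the
#'   manifest block.
#' @export
reportDependencies <- function() {
  pkgs <- c("cartiflow", "Rcpp", "minpack.lm", "methods", "stats")
  vers <- vapply(pkgs, function(p)
    tryCatch(as.character(utils::packageVersion(p)),
             error = function(e) "unknown"), character(1))
  c(r_version = paste(R.version$major, R.version$minor, sep = "."),
    platform = R.version$platform,
    os = paste(Sys.info()[["sysname"]], Sys.info()[["release"]]),
    stats::setNames(vers, paste0("pkg_", pkgs)))
}

#' Workflow run configuration
#'
#' @param stage one of "make-fixtures", "preprocess", "find-reference",
#'   "segment", "morphology", "relaxometry-fit", "relaxometry-dess",
#'   "evaluate".
#' @param imageList an [ImageList-class] or path to a list file (not needed
#'   for "make-fixtures").
#' @param outDir output directory (created when missing).
#' @param cores worker processes; one image per worker.
#' @param seed master seed; every image derives its own seed from it and its
#'   list position, so results never depend on batch order or core count.
#' @param params stage-specific parameter list (see [runStage()]).
#' @return A list of class "RunConfig".
#' @export
runConfig <- function(stage, imageList = NULL, outDir = tempfile("cartiflow"),
                      cores = 1L, seed = 1L, params = list()) {
  stage <- match.arg(stage, c("make-fixtures", "preprocess",
                              "find-reference", "segment", "morphology",
                              "relaxometry-fit", "relaxometry-dess",
                              "evaluate"))
  stopifnot(cores >= 1)
  if (is.character(imageList)) imageList <- parseImageList(imageList)
  structure(list(stage = stage, imageList = imageList, outDir = outDir,
                 cores = as.integer(cores), seed = as.integer(seed),
                 params = params),
            class = "RunConfig")
}

# deterministic per-image seed below 2^31
.image_seed <- function(master, idx) {
  as.integer((as.numeric(master) * 10007 + idx * 101) %% 2147483647)
}

.apply_images <- function(config, n, fun) {
  run1 <- function(i) {
    set.seed(.image_seed(config$seed, i))
    t0 <- Sys.time()
    res <- tryCatch(fun(i), error = function(e)
      list(status = "failed", message = conditionMessage(e), outputs = ""))
    t1 <- Sys.time()
    res$start <- format(t0, "%Y-%m-%d %H:%M:%OS3")
    res$end <- format(t1, "%Y-%m-%d %H:%M:%OS3")
    res
  }
  if (config$cores > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(n), run1, mc.cores = config$cores,
                       mc.preschedule = FALSE)
  } else {
    lapply(seq_len(n), run1)
  }
}

.write_manifest <- function(config, rows, extra = character()) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  man <- file.path(config$outDir,
                   paste0("manifest_", config$stage, ".csv"))
  utils::write.csv(rows, man, row.names = FALSE)
  logf <- file.path(config$outDir, paste0("run_log_", config$stage, ".txt"))
  dep <- reportDependencies()
  lines <- c(paste0("stage: ", config$stage),
             paste0("seed: ", config$seed),
             paste0("cores: ", config$cores),
             paste0("out_dir: ", config$outDir),
             vapply(names(config$params), function(k)
               paste0("param_", k, ": ",
                      paste(format(config$params[[k]]), collapse = " ")),
               character(1)),
             extra,
             "dependencies:",
             paste0("  ", names(dep), ": ", dep))
  writeLines(lines, logf)
  list(manifest = man, log = logf)
}

.out_path <- function(config, input, suffix) {
  file.path(config$outDir,
            paste0(sub("\\.mha$", "", basename(input)), suffix))
}

#' Run one workflow stage over an image list
#'
#' Images are processed independently (optionally across `cores` worker
#' processes, one image per worker); a failure on one image is logged as a
#' failed manifest row and the batch continues. All outputs, CSV tables and
#' the manifest/log pair are written under `config$outDir`. Results are
#' identical for any core count because every image derives its seed from
#' the master seed and its list position.
#'
#' Stage parameters (`config$params`):
#' \describe{
#'   \item{make-fixtures}{`dim`, `spacing`, `noiseSigma` for
#'     [makePhantomCohort()]; writes images, masks, `imagelist.txt` and
#'     `truth.csv`.}
#'   \item{preprocess}{`config` (a [preprocessConfig()]), `intensity`
#'     (default TRUE); writes `*_prep.mha`.}
#'   \item{find-reference}{`seedIndex`, `maxIterations`, `control`
#'     (a [regControl()]); writes `reference_search.csv`.}
#'   \item{segment}{`mode`, `control`; the record with role "reference"
#'     provides the atlas (femur + cartilage masks); writes
#'     `*_cart_mask.mha` and `quality.csv` when ground truth is present
#'     (NA rows otherwise).}
#'   \item{morphology}{per-record cartilage masks are analyzed; writes
#'     per-image `*_thickness.csv`, a `morphology_summary.csv` and PNG
#'     maps.}
#'   \item{relaxometry-fit}{`times`, `kind`, `method` ("exponential" or
#'     "linear"), `align` (default FALSE), `bounds`; each record's
#'     image_path is a directory of per-time `.mha` volumes (ascending
#'     time order) or a multi-echo DICOM series; writes `*_map.mha`,
#'     `relaxometry_summary.csv` and a QC PNG.}
#'   \item{relaxometry-dess}{`tr`, `te`, `flip`, `bounds`; image_path is a
#'     directory holding the two echoes; same outputs.}
#'   \item{evaluate}{image_path = segmented mask, cartilage_mask_path =
#'     ground truth; writes `quality.csv`.}
#' }
#'
#' @param config a [runConfig()] list.
#' @return list with `manifest` (data.frame), `files` (manifest/log paths)
#'   and stage-specific results.
#' @export
runStage <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  switch(config$stage,
         "make-fixtures" = .stage_fixtures(config),
         "preprocess" = .stage_preprocess(config),
         "find-reference" = .stage_findref(config),
         "segment" = .stage_segment(config),
         "morphology" = .stage_morphology(config),
         "relaxometry-fit" = .stage_relax_fit(config),
         "relaxometry-dess" = .stage_relax_dess(config),
         "evaluate" = .stage_evaluate(config))
}

.records_or_stop <- function(config) {
  il <- config$imageList
  if (is.null(il) || !length(il)) stop("empty ImageList for stage ",
                                       config$stage)
  imageRecords(il)
}

.stage_fixtures <- function(config) {
  p <- config$params
  cohort <- makePhantomCohort(dim = p$dim %||% c(24L, 120L, 120L),
                              spacing = p$spacing %||% c(1, 0.5, 0.5),
                              noiseSigma = p$noiseSigma %||% 2,
                              seed = config$seed)
  rows <- list()
  paths <- character(0)
  for (i in seq_along(cohort)) {
    ip <- file.path(config$outDir, sprintf("phantom%d.mha", i))
    fp <- file.path(config$outDir, sprintf("phantom%d_femur.mha", i))
    cp <- file.path(config$outDir, sprintf("phantom%d_cart.mha", i))
    writeImage(cohort[[i]]$image, ip)
    writeImage(cohort[[i]]$femurMask, fp)
    writeImage(cohort[[i]]$cartilageMask, cp)
    paths <- c(paths, ip)
    rows[[i]] <- data.frame(image = ip,
                            outputs = paste(fp, cp, sep = ";"),
                            status = "ok", message = "")
  }
  il <- imageList(paths,
                  femur_mask_path = sub("\\.mha$", "_femur.mha", paths),
                  cartilage_mask_path = sub("\\.mha$", "_cart.mha", paths))
  writeImageList(il, file.path(config$outDir, "imagelist.txt"))
  utils::write.csv(attr(cohort, "truth"),
                   file.path(config$outDir, "truth.csv"), row.names = FALSE)
  files <- .write_manifest(config, do.call(rbind, rows))
  list(manifest = do.call(rbind, rows), files = files,
       imageList = il, cohort = cohort)
}

.stage_preprocess <- function(config) {
  recs <- .records_or_stop(config)
  pcfg <- config$params$config %||% preprocessConfig()
  intensity <- config$params$intensity %||% TRUE
  res <- .apply_images(config, nrow(recs), function(i) {
    img <- readImage(recs$image_path[i])
    out <- preprocessImage(img, recs$laterality[i], pcfg, intensity)
    op <- .out_path(config, recs$image_path[i], "_prep.mha")
    writeImage(out, op)
    list(status = "ok", message = paste(attr(out, "steps"), collapse = ">"),
         outputs = op)
  })
  rows <- do.call(rbind, lapply(seq_along(res), function(i)
    data.frame(image = recs$image_path[i], outputs = res[[i]]$outputs,
               status = res[[i]]$status, message = res[[i]]$message,
               start = res[[i]]$start %||% "", end = res[[i]]$end %||% "")))
  files <- .write_manifest(config, rows,
                           extra = paste0("pipeline_order: ",
                                          "bias>rescale>smooth"))
  list(manifest = rows, files = files)
}

.stage_findref <- function(config) {
  recs <- .records_or_stop(config)
  if (any(is.na(recs$femur_mask_path)))
    stop("find-reference requires a femur mask for every record")
  images <- lapply(recs$image_path, readImage)
  masks <- lapply(recs$femur_mask_path, function(p) {
    m <- readImage(p)
    BinaryMask(m@voxels, m@spacing, m@origin, m@direction)
  })
  ctl <- config$params$control %||% regControl(seed = config$seed)
  fr <- findReference(images, masks,
                      seedIndex = config$params$seedIndex %||% 1L,
                      maxIterations = config$params$maxIterations %||% 10L,
                      control = ctl)
  utils::write.csv(fr$state,
                   file.path(config$outDir, "reference_search.csv"),
                   row.names = FALSE)
  rows <- data.frame(image = recs$image_path,
                     outputs = "reference_search.csv",
                     status = "ok",
                     message = paste0("reference=", fr$referenceIndex))
  files <- .write_manifest(config, rows,
                           extra = paste0("reference_index: ",
                                          fr$referenceIndex))
  list(manifest = rows, files = files, reference = fr)
}

.read_mask <- function(path) {
  m <- readImage(path)
  BinaryMask(round(m@voxels), m@spacing, m@origin, m@direction)
}

.stage_segment <- function(config) {
  recs <- .records_or_stop(config)
  mode <- config$params$mode %||% "intersubject"
  refrow <- which(recs$role == "reference")
  if (length(refrow) != 1L)
    stop("segment stage needs exactly one record with role 'reference'")
  reference <- readImage(recs$image_path[refrow])
  refCart <- .read_mask(recs$cartilage_mask_path[refrow])
  refFemur <- if (!is.na(recs$femur_mask_path[refrow]))
    .read_mask(recs$femur_mask_path[refrow]) else NULL
  moving <- setdiff(seq_len(nrow(recs)), refrow)
  ctl <- config$params$control
  res <- .apply_images(config, length(moving), function(j) {
    i <- moving[j]
    target <- readImage(recs$image_path[i])
    ctl_i <- ctl %||% {
      base <- if (mode == "multimodal") regControl(metric = "mi")
              else regControl()
      base$seed <- .image_seed(config$seed, i)
      base
    }
    seg <- segmentCartilage(reference, refCart, target, mode,
                            referenceFemur = refFemur, control = ctl_i)
    op <- .out_path(config, recs$image_path[i], "_cart_mask.mha")
    writeImage(seg$mask, op)
    q <- if (!is.na(recs$cartilage_mask_path[i])) {
      gt <- .read_mask(recs$cartilage_mask_path[i])
      c(dsc = dice(seg$mask, gt), asd = averageSurfaceDistance(seg$mask, gt))
    } else c(dsc = NA_real_, asd = NA_real_)
    list(status = if (seg$failed) "failed" else "ok",
         message = paste(seg$stagesApplied, collapse = "+"),
         outputs = op, dsc = q[["dsc"]], asd = q[["asd"]])
  })
  qual <- data.frame(
    image_id = basename(recs$image_path[moving]),
    dsc = vapply(res, function(r) r$dsc %||% NA_real_, numeric(1)),
    asd = vapply(res, function(r) r$asd %||% NA_real_, numeric(1)),
    failed = vapply(res, function(r) !identical(r$status, "ok"), logical(1)))
  qual$failed <- qual$failed | (!is.na(qual$dsc) & qual$dsc < 0.6)
  utils::write.csv(qual, file.path(config$outDir, "quality.csv"),
                   row.names = FALSE)
  rows <- do.call(rbind, lapply(seq_along(res), function(j)
    data.frame(image = recs$image_path[moving[j]],
               outputs = res[[j]]$outputs %||% "",
               status = res[[j]]$status, message = res[[j]]$message %||% "",
               start = res[[j]]$start %||% "", end = res[[j]]$end %||% "")))
  files <- .write_manifest(config, rows,
                           extra = c(paste0("mode: ", mode),
                                     paste0("stages: ",
                                            paste(.mode_models(mode),
                                                  collapse = "+"))))
  list(manifest = rows, files = files, quality = qual)
}

.stage_morphology <- function(config) {
  recs <- .records_or_stop(config)
  if (any(is.na(recs$cartilage_mask_path)))
    stop("morphology stage requires a cartilage mask for every record")
  res <- .apply_images(config, nrow(recs), function(i) {
    mask <- .read_mask(recs$cartilage_mask_path[i])
    surf <- morphologyAnalysis(mask)
    summ <- morphologySummary(surf, mask)
    csv <- .out_path(config, recs$cartilage_mask_path[i], "_thickness.csv")
    png <- .out_path(config, recs$cartilage_mask_path[i], "_thickness.png")
    writeThicknessMap(surf, csv, png)
    list(status = "ok", message = "", outputs = csv,
         mean_thickness = summ$mean_thickness_mm,
         sd_thickness = summ$sd_thickness_mm, volume = summ$volume_mm3)
  })
  summary_df <- data.frame(
    image_id = basename(recs$cartilage_mask_path),
    mean_thickness_mm = vapply(res, function(r)
      r$mean_thickness %||% NA_real_, numeric(1)),
    sd_thickness_mm = vapply(res, function(r)
      r$sd_thickness %||% NA_real_, numeric(1)),
    volume_mm3 = vapply(res, function(r) r$volume %||% NA_real_, numeric(1)))
  utils::write.csv(summary_df,
                   file.path(config$outDir, "morphology_summary.csv"),
                   row.names = FALSE)
  rows <- do.call(rbind, lapply(seq_along(res), function(i)
    data.frame(image = recs$cartilage_mask_path[i],
               outputs = res[[i]]$outputs %||% "",
               status = res[[i]]$status, message = res[[i]]$message %||% "",
               start = res[[i]]$start %||% "", end = res[[i]]$end %||% "")))
  files <- .write_manifest(config, rows)
  list(manifest = rows, files = files, summary = summary_df)
}

# read a decay series from a directory: multi-echo DICOM, or .mha volumes
# sorted by the trailing number in their names (the acquisition time in ms)
.read_series_dir <- function(path, kind, times = NULL) {
  mha <- list.files(path, pattern = "\\.mha$", full.names = TRUE)
  if (length(mha) >= 2L) {
    tn <- as.numeric(sub(".*?([0-9]+(\\.[0-9]+)?)\\.mha$", "\\1", mha))
    if (any(is.na(tn))) {
      if (is.null(times))
        stop("cannot infer acquisition times from file names in ", path,
             "; pass params$times")
      ord <- order(times); tn <- times
    } else ord <- order(tn)
    vols <- lapply(mha[ord], readImage)
    return(decaySeries(vols, sort(tn), kind))
  }
  vols <- readDicomSeries(path)
  tms <- times %||% attr(vols, "times")
  if (is.null(tms) || any(is.na(tms)))
    stop("DICOM series in ", path, " carries no echo times; pass ",
         "params$times")
  decaySeries(vols, tms, kind)
}

.qc_png <- function(map, path) {
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  k <- ceiling(dim(map)[1] / 2)
  sl <- map@voxels[k, , ]
  sl[!is.finite(sl)] <- 0
  graphics::image(sl, col = grDevices::hcl.colors(64, "viridis"),
                  main = "mid-slice relaxation map", useRaster = TRUE)
}

.stage_relax_fit <- function(config) {
  recs <- .records_or_stop(config)
  p <- config$params
  method <- p$method %||% "exponential"
  res <- .apply_images(config, nrow(recs), function(i) {
    series <- .read_series_dir(recs$image_path[i], p$kind %||% "T2w",
                               p$times)
    if (isTRUE(p$align)) series <- alignSeries(series)
    mask <- if (!is.na(recs$cartilage_mask_path[i]))
      .read_mask(recs$cartilage_mask_path[i]) else NULL
    fit <- if (method == "linear")
      fitLinear(series, mask, p$bounds %||% c(0, 200))
    else fitExponential(series, mask, p$bounds %||% c(0, 200))
    op <- file.path(config$outDir,
                    paste0(basename(recs$image_path[i]), "_map.mha"))
    tb <- fit@tbMap
    tb@voxels[fit@validMask@voxels == 0] <- 0 # sentinel for file output
    writeImage(tb, op)
    .qc_png(tb, sub("\\.mha$", ".png", op))
    st <- if (is.null(mask)) {
      allm <- BinaryMask(array(1, dim(fit@tbMap)),
                         spacing = fit@tbMap@spacing,
                         origin = fit@tbMap@origin,
                         direction = fit@tbMap@direction)
      mapStatistics(fit, allm)
    } else mapStatistics(fit, mask)
    list(status = "ok", message = method, outputs = op,
         mean_ms = st$mean_ms, sd_ms = st$sd_ms, n_voxels = st$n_voxels)
  })
  summary_df <- data.frame(
    image_id = basename(recs$image_path),
    method = method,
    mean_ms = vapply(res, function(r) r$mean_ms %||% NA_real_, numeric(1)),
    sd_ms = vapply(res, function(r) r$sd_ms %||% NA_real_, numeric(1)),
    n_voxels = vapply(res, function(r) r$n_voxels %||% NA_real_, numeric(1)))
  utils::write.csv(summary_df,
                   file.path(config$outDir, "relaxometry_summary.csv"),
                   row.names = FALSE)
  rows <- do.call(rbind, lapply(seq_along(res), function(i)
    data.frame(image = recs$image_path[i], outputs = res[[i]]$outputs %||% "",
               status = res[[i]]$status, message = res[[i]]$message %||% "",
               start = res[[i]]$start %||% "", end = res[[i]]$end %||% "")))
  files <- .write_manifest(config, rows)
  list(manifest = rows, files = files, summary = summary_df)
}

.stage_relax_dess <- function(config) {
  recs <- .records_or_stop(config)
  p <- config$params
  params <- dessParams(p$tr %||% 16.32, p$te %||% 4.7, p$flip %||% 25)
  res <- .apply_images(config, nrow(recs), function(i) {
    mha <- sort(list.files(recs$image_path[i], pattern = "\\.mha$",
                           full.names = TRUE))
    if (length(mha) != 2L)
      stop("DESS record directory must hold exactly two echo volumes: ",
           recs$image_path[i])
    e1 <- readImage(mha[1]); e2 <- readImage(mha[2])
    mask <- if (!is.na(recs$cartilage_mask_path[i]))
      .read_mask(recs$cartilage_mask_path[i]) else NULL
    fit <- t2FromDess(e1, e2, params, mask, p$bounds %||% c(0, 200))
    op <- file.path(config$outDir,
                    paste0(basename(recs$image_path[i]), "_map.mha"))
    tb <- fit@tbMap
    tb@voxels[fit@validMask@voxels == 0] <- 0
    writeImage(tb, op)
    .qc_png(tb, sub("\\.mha$", ".png", op))
    st <- if (is.null(mask)) {
      allm <- BinaryMask(array(1, dim(fit@tbMap)),
                         spacing = fit@tbMap@spacing,
                         origin = fit@tbMap@origin,
                         direction = fit@tbMap@direction)
      mapStatistics(fit, allm)
    } else mapStatistics(fit, mask)
    list(status = "ok", message = "dess", outputs = op,
         mean_ms = st$mean_ms, sd_ms = st$sd_ms, n_voxels = st$n_voxels)
  })
  summary_df <- data.frame(
    image_id = basename(recs$image_path), method = "dess",
    mean_ms = vapply(res, function(r) r$mean_ms %||% NA_real_, numeric(1)),
    sd_ms = vapply(res, function(r) r$sd_ms %||% NA_real_, numeric(1)),
    n_voxels = vapply(res, function(r) r$n_voxels %||% NA_real_, numeric(1)))
  utils::write.csv(summary_df,
                   file.path(config$outDir, "relaxometry_summary.csv"),
                   row.names = FALSE)
  rows <- do.call(rbind, lapply(seq_along(res), function(i)
    data.frame(image = recs$image_path[i], outputs = res[[i]]$outputs %||% "",
               status = res[[i]]$status, message = res[[i]]$message %||% "",
               start = res[[i]]$start %||% "", end = res[[i]]$end %||% "")))
  files <- .write_manifest(config, rows)
  list(manifest = rows, files = files, summary = summary_df)
}

.stage_evaluate <- function(config) {
  recs <- .records_or_stop(config)
  pairs <- lapply(seq_len(nrow(recs)), function(i) {
    nm <- tryCatch(.read_mask(recs$image_path[i]), error = function(e) NULL)
    gt <- if (!is.na(recs$cartilage_mask_path[i]))
      tryCatch(.read_mask(recs$cartilage_mask_path[i]),
               error = function(e) NULL) else NULL
    list(nm = nm, gt = gt, id = basename(recs$image_path[i]))
  })
  df <- evaluateBatch(pairs, file = file.path(config$outDir, "quality.csv"))
  rows <- data.frame(image = recs$image_path, outputs = "quality.csv",
                     status = ifelse(df$failed, "failed", "ok"),
                     message = "")
  files <- .write_manifest(config, rows)
  list(manifest = rows, files = files, quality = df)
}
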