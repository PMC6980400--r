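# Voxelwise relaxometry: mono-exponential S(Ta) = K exp(-Ta/Tb) fitted by
# Levenberg-Marquardt (Tb = T2 for TE series, T1rho for TSL series), the
# fast log-linear alternative, optional rigid motion pre-alignment, and a
# closed-form DESS T2 estimator from a linear extended-phase-graph
# approximation of the two steady-state echoes.

#' Construct a DecaySeries
#'
#' @param volumes list of co-registered [Image3D-class] volumes.
#' @param times acquisition times in ms (TE or TSL), strictly increasing.
#' @param kind "T2w" (times are echo times) or "T1rho" (spin-lock times).
#' @return A [DecaySeries-class].
#' @export
decaySeries <- function(volumes, times, kind = c("T2w", "T1rho")) {
  kind <- match.arg(kind)
  new("DecaySeries", volumes = volumes, times = as.numeric(times),
      kind = kind)
}

#' DESS acquisition parameters
#'
#' @param tr repetition time (ms).
#' @param te echo time (ms).
#' @param flip flip angle (degrees), in (0, 180).
#' @return A validated list of class "DessParams".
#' @export
dessParams <- function(tr, te, flip) {
  stopifnot(tr > 0, te > 0, flip > 0, flip < 180)
  structure(list(tr = tr, te = te, flip = flip), class = "DessParams")
}

#' Rigidly align a decay series for motion correction
#'
#' Registers every lower-time volume to the volume with the highest TE/TSL
#' (rigid, normalized-correlation metric so the decaying global intensity
#' does not bias the alignment). Times are unchanged. A volume whose
#' registration fails is kept unaligned and reported via the
#' `"alignmentFailed"` attribute; the fit can proceed as long as two volumes
#' remain.
#'
#' @param series a [DecaySeries-class].
#' @param control a [regControl()] list (default: rigid-friendly settings
#'   with the "ncc" metric).
#' @return The aligned [DecaySeries-class] (same times, same kind).
#' @export
alignSeries <- function(series, control = NULL) {
  stopifnot(is(series, "DecaySeries"))
  if (is.null(control)) control <- regControl(metric = "ncc", levels = 2L)
  n <- length(series@volumes)
  ref <- series@volumes[[n]] # highest acquisition time
  out <- series@volumes
  failed <- logical(n)
  for (i in seq_len(n - 1L)) {
    ch <- withCallingHandlers(
      registerImages(ref, series@volumes[[i]], models = "rigid",
                     control = control),
      warning = function(w) invokeRestart("muffleWarning"))
    if (ch@failed) {
      failed[i] <- TRUE
      warning("alignment of volume ", i, " failed; volume kept unaligned")
      next
    }
    out[[i]] <- resampleImage(series@volumes[[i]], ch, geometry(ref))
  }
  res <- decaySeries(out, series@times, series@kind)
  attr(res, "alignmentFailed") <- failed
  res
}

# assemble the n_voxels x n_times signal matrix and the fit selection
.series_signal <- function(series, mask, noiseFraction = 0.05) {
  sig <- vapply(series@volumes, function(v) as.vector(v@voxels),
                numeric(length(series@volumes[[1]]@voxels)))
  sel <- rep(TRUE, nrow(sig))
  if (!is.null(mask)) {
    if (!sameGeometry(geometry(mask), geometry(series@volumes[[1]])))
      .stop_geometry_mismatch("decay series and mask")
    sel <- as.vector(mask@voxels) > 0
  }
  # noise floor: drop voxels whose peak signal is tiny versus the series
  floorv <- noiseFraction * stats::quantile(sig, 0.99, names = FALSE)
  sel & (apply(sig, 1, max) >= floorv)
}

.fit_result <- function(series, tb, k, valid, method) {
  g <- geometry(series@volumes[[1]])
  mk <- function(v) Image3D(array(v, g$dim), spacing = g$spacing,
                            origin = g$origin, direction = g$direction)
  new("FitResult", tbMap = mk(tb), kMap = mk(k),
      validMask = BinaryMask(array(as.double(valid), g$dim),
                             spacing = g$spacing, origin = g$origin,
                             direction = g$direction),
      method = method)
}

# closed-form log-linear solution, vectorized over voxels
.loglinear_solve <- function(sig, times) {
  pos <- sig > 0
  ok <- rowSums(pos) == ncol(sig)
  tb <- rep(NA_real_, nrow(sig)); k <- rep(NA_real_, nrow(sig))
  if (any(ok)) {
    L <- log(sig[ok, , drop = FALSE])
    tbar <- mean(times)
    tc <- times - tbar
    stt <- sum(tc^2)
    slope <- as.vector(L %*% tc) / stt
    inter <- rowMeans(L) - slope * tbar
    tb[ok] <- ifelse(slope < 0, -1 / slope, NA_real_)
    k[ok] <- exp(inter)
  }
  list(tb = tb, k = k)
}

#' Voxelwise mono-exponential fit S(Ta) = K exp(-Ta / Tb)
#'
#' Levenberg-Marquardt least squares per voxel (via
#' \code{minpack.lm::nls.lm}), initialized from the log-linear solution
#' (falling back to the peak signal and the mid-range time when the
#' log-linear solution is unavailable). Voxels outside the mask, below the
#' noise floor, with non-convergent fits, or with Tb outside `bounds` are
#' marked invalid (NA in the maps) and excluded from statistics.
#'
#' @param series a [DecaySeries-class].
#' @param mask optional [BinaryMask-class] on the series geometry.
#' @param bounds admissible (low, high] interval for Tb in ms; default
#'   c(0, 200). Out-of-bound fits are invalidated, not clamped, so the
#'   statistics are not distorted.
#' @param noiseFraction voxels whose peak signal is below this fraction of
#'   the series' 99th-percentile signal are excluded (default 0.05).
#' @return A [FitResult-class] with method "exponential".
#' @export
fitExponential <- function(series, mask = NULL, bounds = c(0, 200),
                           noiseFraction = 0.05) {
  stopifnot(is(series, "DecaySeries"))
  times <- series@times
  sig <- vapply(series@volumes, function(v) as.vector(v@voxels),
                numeric(length(series@volumes[[1]]@voxels)))
  sel <- .series_signal(series, mask, noiseFraction)
  if (!any(sel)) stop("no voxels eligible for fitting")
  tb <- rep(NA_real_, nrow(sig)); kk <- rep(NA_real_, nrow(sig))
  init <- .loglinear_solve(sig[sel, , drop = FALSE], times)
  idxs <- which(sel)
  midtb <- mean(range(times))
  for (j in seq_along(idxs)) {
    i <- idxs[j]
    y <- sig[i, ]
    p0 <- c(K = init$k[j], Tb = init$tb[j])
    if (any(!is.finite(p0)) || p0[2] <= 0 || p0[2] > 10 * bounds[2])
      p0 <- c(K = max(y), Tb = midtb)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0,
                         fn = function(p) y - p[1] * exp(-times / p[2]),
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info %in% c(0, 9)) next
    est <- fit$par
    if (!all(is.finite(est)) || est[2] <= bounds[1] || est[2] > bounds[2])
      next
    tb[i] <- est[2]; kk[i] <- est[1]
  }
  valid <- is.finite(tb)
  if (!any(valid)) stop("exponential fit failed on all voxels")
  .fit_result(series, tb, kk, valid, "exponential")
}

#' Voxelwise log-linear fit of the mono-exponential decay
#'
#' Ordinary least squares of ln S on the acquisition time: Tb = -1/slope,
#' K = exp(intercept). Fast but biased under noise because the logarithm
#' transformation alters the noise distribution; voxels with any nonpositive
#' sample are invalid.
#'
#' @inheritParams fitExponential
#' @return A [FitResult-class] with method "linear".
#' @export
fitLinear <- function(series, mask = NULL, bounds = c(0, 200),
                      noiseFraction = 0.05) {
  stopifnot(is(series, "DecaySeries"))
  times <- series@times
  sig <- vapply(series@volumes, function(v) as.vector(v@voxels),
                numeric(length(series@volumes[[1]]@voxels)))
  sel <- .series_signal(series, mask, noiseFraction)
  if (!any(sel)) stop("no voxels eligible for fitting")
  tb <- rep(NA_real_, nrow(sig)); kk <- rep(NA_real_, nrow(sig))
  sol <- .loglinear_solve(sig[sel, , drop = FALSE], times)
  tb[sel] <- sol$tb
  kk[sel] <- sol$k
  bad <- !is.finite(tb) | tb <= bounds[1] | tb > bounds[2]
  tb[bad] <- NA_real_; kk[bad] <- NA_real_
  valid <- is.finite(tb)
  if (!any(valid)) stop("log-linear fit failed on all voxels")
  .fit_result(series, tb, kk, valid, "linear")
}

#' Forward DESS signal-ratio model
#'
#' The linear extended-phase-graph approximation used by this package
#' relates the two DESS echoes by
#' \deqn{S_2 / S_1 = \sin^2(\alpha/2) \exp(-2 (TR - TE) / T_2)}
#' with flip angle \eqn{\alpha}. This single function (with
#' [t2FromDess()], its exact inverse) isolates the approximation so the
#' constant can be revised without touching the rest of the module.
#'
#' @param t2 T2 in ms (positive).
#' @param params a [dessParams()] list.
#' @return The predicted echo ratio S2/S1, in (0, sin^2(alpha/2)).
#' @export
dessRatio <- function(t2, params) {
  stopifnot(inherits(params, "DessParams"), all(t2 > 0))
  k <- sin(params$flip * pi / 180 / 2)^2
  k * exp(-2 * (params$tr - params$te) / t2)
}

#' T2 map from a DESS echo pair
#'
#' Closed-form voxelwise inversion of the linear extended-phase-graph
#' approximation in [dessRatio()]:
#' \deqn{T_2 = -2 (TR - TE) / \ln\big((S_2/S_1) / \sin^2(\alpha/2)\big)}
#' Voxels with S1 <= 0, S2 <= 0, ratio outside the model's valid domain
#' (>= sin^2(alpha/2)) or T2 outside `bounds` are invalid.
#'
#' @param echo1,echo2 co-registered [Image3D-class] echoes (S1, S2).
#' @param params a [dessParams()] list.
#' @param mask optional [BinaryMask-class].
#' @param bounds admissible T2 interval in ms, default c(0, 200).
#' @return A [FitResult-class] with method "dess" (kMap holds S1).
#' @export
t2FromDess <- function(echo1, echo2, params, mask = NULL,
                       bounds = c(0, 200)) {
  stopifnot(is(echo1, "Image3D"), is(echo2, "Image3D"),
            inherits(params, "DessParams"))
  if (!sameGeometry(geometry(echo1), geometry(echo2)))
    .stop_geometry_mismatch("DESS echoes")
  s1 <- as.vector(echo1@voxels); s2 <- as.vector(echo2@voxels)
  sel <- rep(TRUE, length(s1))
  if (!is.null(mask)) {
    if (!sameGeometry(geometry(mask), geometry(echo1)))
      .stop_geometry_mismatch("DESS echoes and mask")
    sel <- as.vector(mask@voxels) > 0
  }
  k <- sin(params$flip * pi / 180 / 2)^2
  ratio <- ifelse(s1 > 0, s2 / s1, NA_real_)
  ok <- sel & is.finite(ratio) & ratio > 0 & ratio < k
  if (any(sel & is.finite(ratio)) && all(ratio[sel & is.finite(ratio)] >= 1))
    stop("echo ratio S2/S1 >= 1 everywhere: unphysical DESS input")
  t2 <- rep(NA_real_, length(s1))
  t2[ok] <- -2 * (params$tr - params$te) / log(ratio[ok] / k)
  bad <- !is.finite(t2) | t2 <= bounds[1] | t2 > bounds[2]
  t2[bad] <- NA_real_
  valid <- is.finite(t2)
  if (!any(valid)) stop("no voxel yields a valid DESS T2")
  kk <- ifelse(valid, s1, NA_real_)
  series_like <- decaySeries(list(echo1, echo2), c(params$te,
                                                   params$te + 1), "T2w")
  .fit_result(series_like, t2, kk, valid, "dess")
}

#' Mean/SD statistics of a fitted map inside a mask
#'
#' Population standard deviation (divisor n), as used for the tabular
#' per-image summaries.
#'
#' @param fit a [FitResult-class].
#' @param mask a [BinaryMask-class] on the map geometry.
#' @return data.frame with mean_ms, sd_ms, n_voxels.
#' @export
mapStatistics <- function(fit, mask) {
  stopifnot(is(fit, "FitResult"), is(mask, "BinaryMask"))
  if (!sameGeometry(geometry(fit@tbMap), geometry(mask)))
    .stop_geometry_mismatch("map and mask")
  sel <- mask@voxels > 0 & fit@validMask@voxels > 0
  v <- fit@tbMap@voxels[sel]
  if (!length(v)) stop("no valid voxels inside the mask")
  data.frame(mean_ms = mean(v),
             sd_ms = sqrt(mean((v - mean(v))^2)),
             n_voxels = length(v))
}
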