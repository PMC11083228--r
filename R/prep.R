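#' @include AllClasses.R utils.R
NULL

#' Detect the bolus-arrival frame of a curve
#'
#' Scans forward through the curve and returns the first frame whose value
#' exceeds the running pre-arrival baseline by five baseline standard
#' deviations. The baseline excludes the first two timepoints (transient
#' non-steady-state frames) and grows with the scan; the threshold needs
#' at least three baseline frames for a usable SD estimate, so the
#' earliest reportable arrival is frame 6 (1-based). If the threshold
#' never fires, the start of
#' the steepest global upslope is returned as a fallback. A flat curve is
#' a detection error.
#'
#' @param curve numeric vector (signal or concentration), length >= 8.
#' @return 1-based arrival frame index.
#' @export
detectArrival <- function(curve) {
  n <- length(curve)
  if (n < 8L)
    .dceError("dceDetectionError", "curve too short for arrival detection")
  if (max(curve) - min(curve) <= 0)
    .dceError("dceDetectionError", "flat curve: no arrival to detect")
  # the running-threshold rule needs >= 3 baseline frames for a usable SD
  # (a shorter baseline makes the 5-SD threshold fire on any excursion),
  # so the earliest reportable arrival is frame 6
  for (k in 6:n) {
    base <- curve[3:(k - 1)]
    m <- mean(base)
    s <- stats::sd(base)
    thr <- m + 5 * s
    # a genuine bolus stays up: require the next frame to confirm
    if (curve[k] > thr && curve[k] > m &&
        (k == n || curve[k + 1] > thr)) return(k)
  }
  # Fallback: frame at the start of the steepest rise.
  d <- diff(curve)
  if (max(d) <= 0)
    .dceError("dceDetectionError", "no upslope found")
  max(4L, which.max(d))
}

#' Compute the per-voxel baseline signal S0
#'
#' Mean signal over the baseline window, which excludes the first two
#' timepoints and ends with the final frame before contrast arrival:
#' frames 3..(arrival - 1) in 1-based indexing.
#'
#' @param series a [DynamicSeries-class].
#' @param arrivalFrame 1-based arrival index (>= 4).
#' @return 3D array of baseline means.
#' @export
computeBaseline <- function(series, arrivalFrame) {
  stopifnot(is(series, "DynamicSeries"))
  if (arrivalFrame < 4L)
    .dceError("dceWindowError",
              "arrival before frame 4 leaves an empty baseline window")
  d <- dim(series@voxels)
  frames <- 3:(min(arrivalFrame, d[4] + 1L) - 1L)
  m <- matrix(series@voxels, nrow = prod(d[1:3]), ncol = d[4])
  s0 <- rowMeans(m[, frames, drop = FALSE])
  array(s0, dim = d[1:3])
}

#' Convert a signal series to contrast-agent concentration
#'
#' Applies the linearized signal model \eqn{C(t) = R\,(S(t) - S_0)/S_0}.
#' With no T1 mapping the scale constant is \eqn{R = 1}, assuming an
#' identical native T1 in lesions and normal tissue, so concentration is
#' unitless. Voxels with nonpositive baseline are flagged invalid (their
#' curves become NaN) rather than raising an error. Negative
#' concentrations from noise are kept, not clipped, to avoid biasing fits
#' near baseline.
#'
#' @param series a [DynamicSeries-class].
#' @param s0 3D baseline array from [computeBaseline()].
#' @param R scale constant, default 1.
#' @param arrivalFrame 1-based arterial arrival index carried along for
#'   downstream windowing.
#' @return a [ConcentrationSeries-class].
#' @export
toConcentration <- function(series, s0, R = 1, arrivalFrame) {
  stopifnot(is(series, "DynamicSeries"))
  d <- dim(series@voxels)
  stopifnot(identical(dim(s0), d[1:3]))
  valid <- is.finite(s0) & s0 > 0
  dim(valid) <- d[1:3]
  s0safe <- ifelse(valid, s0, NA_real_)
  conc <- R * sweep(sweep(series@voxels, 1:3, s0safe, "-"), 1:3, s0safe, "/")
  new("ConcentrationSeries", voxels = conc, dtSeconds = series@dtSeconds,
      arrivalFrame = as.integer(arrivalFrame), valid = valid,
      spacing = series@spacing)
}

#' Extract the arterial input function from an arterial ROI
#'
#' The AIF is the plain mean of the concentration curves over the arterial
#' voxels — no amplitude correction or rescaling is applied — with the
#' arrival frame re-detected on the averaged curve.
#'
#' @param conc a [ConcentrationSeries-class].
#' @param artery an arterial [RoiMask-class].
#' @return an [Aif-class].
#' @export
extractAif <- function(conc, artery) {
  stopifnot(is(conc, "ConcentrationSeries"), is(artery, "RoiMask"))
  d <- dim(conc@voxels)
  if (!identical(dim(artery@voxels), d[1:3]))
    .dceError("dceGeometryError", "artery mask grid mismatch")
  sel <- artery@voxels & conc@valid
  if (!any(sel))
    .dceError("dceEmptyRoiError", "artery ROI has no usable voxels")
  m <- matrix(conc@voxels, nrow = prod(d[1:3]), ncol = d[4])
  values <- colMeans(m[as.vector(sel), , drop = FALSE])
  Aif(values, arrivalFrame = detectArrival(values),
      sourceVoxelCount = sum(sel), dtSeconds = conc@dtSeconds)
}

#' Cut the analysis window from a curve
#'
#' Returns the frames from the arrival frame through `durationS` seconds
#' later (the kinetic analysis uses the first 2 minutes from the onset of
#' enhancement), with time re-origined to zero at arrival. Truncates at
#' the end of the series when the window would run past it.
#'
#' @param curve numeric vector over all dynamics.
#' @param arrivalFrame 1-based arrival index.
#' @param durationS window length in seconds (default 120).
#' @param dtSeconds frame spacing in seconds.
#' @return list with `values`, `timeS` (seconds from arrival), `timeMin`,
#'   `frames` (original 1-based indices) and `truncated` flag.
#' @export
cutWindow <- function(curve, arrivalFrame, durationS = 120, dtSeconds) {
  n <- length(curve)
  last <- arrivalFrame + floor(durationS / dtSeconds)
  truncated <- last > n
  idx <- arrivalFrame:min(last, n)
  timeS <- (seq_along(idx) - 1) * dtSeconds
  list(values = curve[idx], timeS = timeS, timeMin = timeS / 60,
       frames = idx, truncated = truncated)
}
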