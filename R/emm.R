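#' @include AllClasses.R utils.R
NULL

# Empirical mathematical models work on a time axis in dynamics (frame
# counts), matching the units in which their parameters are reported.
# For a curve windowed at the arrival frame, t = 0, 1, 2, ... dynamics.

#' Exponential empirical enhancement model
#'
#' \eqn{C(t) = A (1 - e^{-\alpha (t - t_0)})} for \eqn{t \ge t_0}, zero
#' before: a saturating uptake curve with amplitude A and enhancement rate
#' \eqn{\alpha} per dynamic.
#'
#' @param p named numeric: `A`, `alpha` (1/dynamic), `t0` (dynamics).
#' @param times time grid in dynamics.
#' @return numeric curve.
#' @export
expEmmCurve <- function(p, times) {
  tau <- times - p[["t0"]]
  ifelse(tau >= 0, p[["A"]] * (1 - exp(-p[["alpha"]] * tau)), 0)
}

#' Sigmoidal empirical enhancement model
#'
#' The integral of a Gaussian bump: \eqn{C(t) = A_0\,\Phi((t - A_1)/A_2)}
#' with \eqn{\Phi} the standard normal CDF, so \eqn{A_0} is the plateau
#' amplitude, \eqn{A_1} the center time (half-amplitude point) and
#' \eqn{A_2} the slope width, both in dynamics.
#'
#' @param p named numeric: `A0`, `A1` (dynamics), `A2` (dynamics, > 0).
#' @param times time grid in dynamics.
#' @return numeric curve.
#' @export
sigmoidEmmCurve <- function(p, times) {
  if (p[["A2"]] <= 0)
    .dceError("dceDomainError", "sigmoid width A2 must be > 0")
  p[["A0"]] * stats::pnorm((times - p[["A1"]]) / p[["A2"]])
}

#' Build the uptake-phase weight vector for EMM fitting
#'
#' Weights are 1 over the uptake phase and 0 afterwards, limiting the
#' influence of wash-out. Policies: `fixed_120s` keeps frames within the
#' first 120 s; `to_peak` keeps frames up to and including the curve
#' maximum; the default `max120_peak` keeps frames up to whichever cutoff
#' is later ("1 for at least the first 120 s, or to peak of enhancement").
#' The result is always a contiguous prefix of ones.
#'
#' @param curve windowed concentration curve.
#' @param dtSeconds frame spacing in seconds.
#' @param policy one of "max120_peak", "fixed_120s", "to_peak".
#' @param fixedS cutoff for the fixed policy, seconds.
#' @return integer 0/1 vector, same length as `curve`.
#' @export
buildWeights <- function(curve, dtSeconds,
                         policy = c("max120_peak", "fixed_120s", "to_peak"),
                         fixedS = 120) {
  policy <- match.arg(policy)
  n <- length(curve)
  timeS <- (seq_len(n) - 1) * dtSeconds
  cutFixed <- max(which(timeS <= fixedS))
  cutPeak <- which.max(curve)
  cut <- switch(policy,
                fixed_120s = cutFixed,
                to_peak = cutPeak,
                max120_peak = max(cutFixed, cutPeak))
  as.integer(seq_len(n) <= cut)
}

# Interpolated time at which the curve first crosses `level`, in dynamics
# (0-origin). NA when never crossed.
.crossingTime <- function(curve, level) {
  idx <- which(curve >= level)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  if (i == 1L) return(0)
  frac <- (level - curve[i - 1]) / (curve[i] - curve[i - 1])
  (i - 2) + frac
}

#' Starting estimates for the exponential EMM
#'
#' From an initial look at the baseline and ending signal of the weighted
#' window: the amplitude is the mean of the last 10% of weighted frames,
#' the rate comes from the time to half amplitude
#' (\eqn{\alpha = \ln 2 / t_{1/2}}), and the arrival offset is 0 (the
#' window is already re-origined at arrival).
#'
#' @param curve windowed concentration curve (length >= 5).
#' @param weights 0/1 weight vector (default all ones).
#' @return list with `params` (named numeric A, alpha, t0) and
#'   `degenerate` flag (TRUE for flat curves).
#' @export
initialEstimatesExp <- function(curve, weights = NULL) {
  n <- length(curve)
  if (n < 5L) .dceError("dceWindowError", "curve too short for starts")
  if (is.null(weights)) weights <- rep(1L, n)
  w <- curve[weights > 0]
  nTail <- max(1L, ceiling(0.1 * length(w)))
  A <- mean(utils::tail(w, nTail))
  if (!is.finite(A) || max(w) - min(w) == 0 || A <= 0) {
    return(list(params = c(A = max(A, 0), alpha = 0.1, t0 = 0),
                degenerate = TRUE))
  }
  tHalf <- .crossingTime(w, A / 2)
  alpha <- if (is.finite(tHalf) && tHalf > 0) log(2) / tHalf else 0.5
  list(params = c(A = A, alpha = min(alpha, 5), t0 = 0), degenerate = FALSE)
}

#' Starting estimates for the sigmoidal EMM
#'
#' Amplitude from the late weighted frames, center \eqn{A_1} at the
#' half-amplitude crossing, width \eqn{A_2 = (t_{90\%} - t_{10\%})/2.563}
#' (the 10-90% rise of a normal CDF spans 2.563 standard deviations).
#'
#' @inheritParams initialEstimatesExp
#' @return list with `params` (named numeric A0, A1, A2) and `degenerate`.
#' @export
initialEstimatesSigmoid <- function(curve, weights = NULL) {
  n <- length(curve)
  if (n < 5L) .dceError("dceWindowError", "curve too short for starts")
  if (is.null(weights)) weights <- rep(1L, n)
  w <- curve[weights > 0]
  nTail <- max(1L, ceiling(0.1 * length(w)))
  A0 <- mean(utils::tail(w, nTail))
  if (!is.finite(A0) || max(w) - min(w) == 0 || A0 <= 0) {
    return(list(params = c(A0 = max(A0, 0), A1 = length(w) / 2, A2 = 5),
                degenerate = TRUE))
  }
  t50 <- .crossingTime(w, 0.5 * A0)
  t10 <- .crossingTime(w, 0.1 * A0)
  t90 <- .crossingTime(w, 0.9 * A0)
  A1 <- if (is.finite(t50)) t50 else length(w) / 2
  A2 <- if (is.finite(t10) && is.finite(t90) && t90 > t10)
    (t90 - t10) / 2.563 else max(A1 / 2, 1)
  list(params = c(A0 = A0, A1 = A1, A2 = A2), degenerate = FALSE)
}

.wlsFit <- function(curve, weights, model, par0, lower, upper) {
  sel <- weights > 0
  if (sum(sel) < 4L)
    .dceError("dceFitError", "fewer than 4 weighted frames")
  times <- seq_along(curve) - 1
  resid <- function(p) {
    sqrt(weights[sel]) * (curve[sel] - model(p, times[sel]))
  }
  ssr0 <- sum(resid(par0)^2)
  fit <- minpack.lm::nls.lm(par = par0, fn = resid, lower = lower,
                            upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  list(par = fit$par, ssr = fit$deviance, ssrStart = ssr0,
       converged = fit$info %in% 1:4 && fit$deviance <= ssr0 + 1e-12)
}

#' Fit the exponential EMM by weighted bounded least squares
#'
#' Optimizer bounds are loose (\eqn{\alpha \in (0, 10]}); the credible
#' range \eqn{\alpha \in (0, 1]} is applied afterwards as a validity flag.
#' Amplitude and arrival time are unconstrained by the credible ranges.
#'
#' @param curve windowed concentration curve (t = 0, 1, ... dynamics).
#' @param weights 0/1 uptake weights from [buildWeights()]; default
#'   all ones.
#' @param start optional named starting estimates; computed via
#'   [initialEstimatesExp()] when absent.
#' @return list with `params` (A, alpha, t0), `ssr`, `converged`,
#'   `valid` (alpha within its credible range), `degenerateStart`.
#' @export
fitExpEmm <- function(curve, weights = NULL, start = NULL) {
  n <- length(curve)
  if (is.null(weights)) weights <- rep(1L, n)
  degen <- FALSE
  if (is.null(start)) {
    s <- initialEstimatesExp(curve, weights)
    start <- s$params
    degen <- s$degenerate
  }
  fit <- .wlsFit(curve, weights, expEmmCurve,
                 par0 = c(A = start[["A"]], alpha = start[["alpha"]],
                          t0 = start[["t0"]]),
                 lower = c(0, 1e-6, -10), upper = c(Inf, 10, n))
  params <- c(A = fit$par[["A"]], alpha = fit$par[["alpha"]],
              t0 = fit$par[["t0"]])
  list(params = params, ssr = fit$ssr, converged = fit$converged,
       valid = fit$converged && !degen && .inRange(params[["alpha"]], "alpha"),
       degenerateStart = degen)
}

#' Fit the sigmoidal EMM by weighted bounded least squares
#'
#' The center is fitted in window coordinates, so the reported `A1` is
#' already the center time relative to contrast arrival
#' (\eqn{A_1 - T_0}). Credible ranges \eqn{A_1 - T_0 \in (0, 100]} and
#' \eqn{A_2 \in (0, 100]} dynamics become the validity flag.
#'
#' @inheritParams fitExpEmm
#' @return list with `params` (A0, A1, A2), `ssr`, `converged`, `valid`,
#'   `degenerateStart`.
#' @export
fitSigmoidEmm <- function(curve, weights = NULL, start = NULL) {
  n <- length(curve)
  if (is.null(weights)) weights <- rep(1L, n)
  degen <- FALSE
  if (is.null(start)) {
    s <- initialEstimatesSigmoid(curve, weights)
    start <- s$params
    degen <- s$degenerate
  }
  fit <- .wlsFit(curve, weights, sigmoidEmmCurve,
                 par0 = c(A0 = start[["A0"]], A1 = start[["A1"]],
                          A2 = start[["A2"]]),
                 lower = c(0, -50, 1e-6), upper = c(Inf, n + 50, 1000))
  params <- c(A0 = fit$par[["A0"]], A1 = fit$par[["A1"]],
              A2 = fit$par[["A2"]])
  list(params = params, ssr = fit$ssr, converged = fit$converged,
       valid = fit$converged && !degen &&
         .inRange(params[["A1"]], "a1_minus_t0") &&
         .inRange(params[["A2"]], "a2"),
       degenerateStart = degen)
}

#' Time to peak of a windowed curve
#'
#' Frame index of the curve maximum minus the arrival index, in dynamics.
#' Ties break to the earliest maximum, so a constant curve has TTP 0. TTP
#' is invariant to positive affine rescaling of the curve.
#'
#' @param curve windowed concentration curve.
#' @param arrivalFrame 1-based index of the arrival frame within `curve`
#'   (1 for a curve already windowed at arrival).
#' @return time to peak in dynamics (integer-valued numeric).
#' @export
computeTtp <- function(curve, arrivalFrame = 1L) {
  if (!length(curve)) .dceError("dceWindowError", "empty window")
  as.numeric(which.max(curve) - arrivalFrame)
}

.emmMapSpec <- list(
  a = "none", alpha = "1/dynamic", t0 = "dynamics", a0 = "none",
  a1_minus_t0 = "dynamics", a2 = "dynamics", ttp = "dynamics")

#' Fit the empirical models and TTP voxelwise
#'
#' Runs [fitExpEmm()], [fitSigmoidEmm()] and [computeTtp()] over every
#' voxel in `mask`, on the analysis window starting at the arrival frame,
#' with uptake weights from [buildWeights()].
#'
#' @param conc a [ConcentrationSeries-class].
#' @param mask optional [RoiMask-class] or 3D logical array.
#' @param windowS analysis window in seconds.
#' @param policy weighting policy, see [buildWeights()].
#' @return named list of [ParameterMap-class]: a, alpha, t0, a0,
#'   a1_minus_t0, a2, ttp.
#' @export
fitEmmVolume <- function(conc, mask = NULL, windowS = 120,
                         policy = "max120_peak") {
  stopifnot(is(conc, "ConcentrationSeries"))
  d <- dim(conc@voxels)
  sel <- if (is.null(mask)) conc@valid
         else (if (is(mask, "RoiMask")) mask@voxels else mask) & conc@valid
  maps <- lapply(names(.emmMapSpec), function(p) {
    ParameterMap(p, array(NaN, d[1:3]), unit = .emmMapSpec[[p]],
                 valid = array(FALSE, d[1:3]))
  })
  names(maps) <- names(.emmMapSpec)
  m <- matrix(conc@voxels, nrow = prod(d[1:3]), ncol = d[4])
  frames <- cutWindow(m[1, ], conc@arrivalFrame, windowS,
                      conc@dtSeconds)$frames
  for (v in which(sel)) {
    curve <- m[v, frames]
    wts <- buildWeights(curve, conc@dtSeconds, policy)
    ef <- tryCatch(fitExpEmm(curve, wts), dceError = function(e) NULL)
    sf <- tryCatch(fitSigmoidEmm(curve, wts), dceError = function(e) NULL)
    if (!is.null(ef)) {
      maps$a@values[v] <- ef$params[["A"]]
      maps$a@valid[v] <- ef$converged
      maps$alpha@values[v] <- ef$params[["alpha"]]
      maps$alpha@valid[v] <- ef$valid
      maps$t0@values[v] <- ef$params[["t0"]]
      maps$t0@valid[v] <- ef$converged
    }
    if (!is.null(sf)) {
      maps$a0@values[v] <- sf$params[["A0"]]
      maps$a0@valid[v] <- sf$converged
      maps$a1_minus_t0@values[v] <- sf$params[["A1"]]
      maps$a1_minus_t0@valid[v] <- sf$valid
      maps$a2@values[v] <- sf$params[["A2"]]
      maps$a2@valid[v] <- sf$valid
    }
    maps$ttp@values[v] <- computeTtp(curve)
    maps$ttp@valid[v] <- TRUE
  }
  for (p in names(maps)) maps[[p]] <- ParameterMap(
    p, maps[[p]]@values, unit = .emmMapSpec[[p]], valid = maps[[p]]@valid)
  maps
}
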