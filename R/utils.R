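#' @include AllClasses.R
NULL

# Structured conditions so pipeline stages can fail soft per voxel/ROI while
# file-level problems fail hard.
.dceError <- function(class, message, call = sys.call(-1)) {
  stop(structure(class = c(class, "dceError", "error", "condition"),
                 list(message = message, call = call)))
}

# Physiologically credible acceptance ranges per parameter, used to mask
# fitted values before ROI summarization. EMM time parameters are in
# dynamics (frame counts); kinetic times in minutes; rates in 1/min.
.paramRanges <- data.frame(
  parameter = c("vp", "ps", "fp", "tc", "mttp", "e", "ktrans",
                "a", "alpha", "t0", "a0", "a1_minus_t0", "a2", "ttp"),
  unit = c("none", "1/min", "1/min", "min", "min", "none", "1/min",
           "none", "1/dynamic", "dynamics", "none", "dynamics", "dynamics",
           "dynamics"),
  lower = c(0, 0, 0, 0, 0, 0, 0, -Inf, 0, -Inf, -Inf, 0, 0, -Inf),
  upper = c(10, 10, 10, 5, 5, 1, 10, Inf, 1, Inf, Inf, 100, 100, Inf),
  lowerClosed = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                  TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE),
  upperClosed = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE,
                  TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

#' Physiologically credible parameter ranges
#'
#' The acceptance ranges applied as validity masks to fitted parameter
#' values before ROI summarization. Two-compartment uptake parameters:
#' \eqn{v_p \in [0,10]}, \eqn{PS \in (0,10]}, \eqn{F_p \in [0,10]},
#' \eqn{T_c, MTT_p \in [0,5)}, \eqn{E \in [0,1]},
#' \eqn{K^{trans} \in [0,10]}; exponential model rate
#' \eqn{\alpha \in (0,1]} per dynamic; sigmoid center \eqn{A_1 - T_0} and
#' slope width \eqn{A_2 \in (0,100]} dynamics. Amplitudes, arrival times
#' and time-to-peak are unconstrained. Note the \eqn{v_p} upper bound is
#' deliberately not the physical limit of 1, because the unscaled arterial
#' input function leaves an arbitrary global amplitude in the fits.
#'
#' @return data.frame with columns parameter, unit, lower, upper,
#'   lowerClosed, upperClosed.
#' @export
parameterRanges <- function() .paramRanges

# Vectorized range check; NA/NaN/Inf are always out of range.
.inRange <- function(values, parameter) {
  r <- .paramRanges[.paramRanges$parameter == parameter, ]
  if (nrow(r) != 1L)
    .dceError("dceConfigError", sprintf("unknown parameter '%s'", parameter))
  ok <- is.finite(values)
  lo <- if (r$lowerClosed) values >= r$lower else values > r$lower
  hi <- if (r$upperClosed) values <= r$upper else values < r$upper
  ok & lo & hi
}

.paramUnit <- function(parameter) {
  .paramRanges$unit[match(parameter, .paramRanges$parameter)]
}

# Parameters entering cohort statistics (amplitudes A, A0 and arrival t0
# show negligible tissue contrast and are excluded from analysis).
.analyzedParameters <- c("vp", "ps", "fp", "mttp", "tc", "e", "ktrans",
                         "alpha", "a1_minus_t0", "a2", "ttp")

#' Parameters entering the cohort statistical analyses
#'
#' The seven two-compartment uptake parameters, the exponential rate
#' \eqn{\alpha}, the sigmoid parameters \eqn{A_1 - T_0} and \eqn{A_2}, and
#' time-to-peak. The EMM amplitudes and arrival time are fitted but not
#' analyzed.
#'
#' @return character vector of canonical parameter keys.
#' @export
analyzedParameters <- function() .analyzedParameters

# Uniform-grid guard used by the convolution code.
.checkUniformGrid <- function(times, tol = 1e-6) {
  if (length(times) < 2L) return(invisible(TRUE))
  d <- diff(times)
  if (max(abs(d - d[1])) > tol * abs(d[1]))
    .dceError("dceGridError", "time grid must be uniform")
  invisible(TRUE)
}
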