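#' @import methods
NULL

#' DynamicSeries: a 4D dynamic contrast-enhanced signal series
#'
#' Container for a 4D (x, y, z, t) signal-intensity array acquired on a
#' uniform temporal grid. Frame times are \eqn{t_k = (k-1)\,dt} seconds with
#' the first acquired frame at \eqn{t = 0}. All kinetic computations convert
#' to minutes internally.
#'
#' @slot voxels 4D numeric array of nonnegative signal intensities.
#' @slot dtSeconds frame spacing in seconds (> 0).
#' @slot spacing voxel spacing in mm, length 3.
#'
#' @seealso [readDynamicSeries()], [toConcentration()]
#' @export
setClass("DynamicSeries",
  representation(voxels = "array", dtSeconds = "numeric", spacing = "numeric"),
  prototype(spacing = c(1, 1, 1))
)

setValidity("DynamicSeries", function(object) {
  msg <- NULL
  d <- dim(object@voxels)
  if (length(d) != 4L) msg <- c(msg, "voxels must be a 4D array (x, y, z, t)")
  else if (d[4] < 3L) msg <- c(msg, "a dynamic series needs at least 3 frames")
  if (length(object@dtSeconds) != 1L || !is.finite(object@dtSeconds) ||
      object@dtSeconds <= 0)
    msg <- c(msg, "dtSeconds must be a single positive number")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive voxel dimensions (mm)")
  if (is.null(msg)) TRUE else msg
})

#' @param voxels 4D numeric array (x, y, z, t).
#' @param dtSeconds frame spacing in seconds.
#' @param spacing voxel spacing in mm (length 3).
#' @rdname DynamicSeries-class
#' @export
DynamicSeries <- function(voxels, dtSeconds, spacing = c(1, 1, 1)) {
  new("DynamicSeries", voxels = voxels, dtSeconds = as.numeric(dtSeconds),
      spacing = as.numeric(spacing))
}

#' ConcentrationSeries: a 4D contrast-agent concentration series
#'
#' The result of converting a [DynamicSeries-class] to contrast-agent
#' concentration via \eqn{C(t) = R\,(S(t) - S_0)/S_0}. Concentration is
#' unitless under the default \eqn{R = 1}. Voxels with a nonpositive
#' baseline are flagged invalid rather than dropped.
#'
#' @slot voxels 4D numeric concentration array.
#' @slot dtSeconds frame spacing in seconds.
#' @slot arrivalFrame 1-based index of the first frame of contrast arrival
#'   in the artery (>= 4 so that the baseline window, which excludes the
#'   first two timepoints, contains at least one frame).
#' @slot valid 3D logical array; FALSE where the baseline was unusable.
#' @slot spacing voxel spacing in mm.
#'
#' @export
setClass("ConcentrationSeries",
  representation(voxels = "array", dtSeconds = "numeric",
                 arrivalFrame = "integer", valid = "array",
                 spacing = "numeric"),
  prototype(spacing = c(1, 1, 1))
)

setValidity("ConcentrationSeries", function(object) {
  msg <- NULL
  d <- dim(object@voxels)
  if (length(d) != 4L) msg <- c(msg, "voxels must be a 4D array")
  if (length(object@arrivalFrame) != 1L || object@arrivalFrame < 4L)
    msg <- c(msg, "arrivalFrame must be a single index >= 4")
  if (!is.logical(object@valid) || !identical(dim(object@valid), d[1:3]))
    msg <- c(msg, "valid must be a 3D logical array matching the spatial grid")
  if (length(object@dtSeconds) != 1L || object@dtSeconds <= 0)
    msg <- c(msg, "dtSeconds must be positive")
  if (is.null(msg)) TRUE else msg
})

#' RoiMask: a 3D binary region-of-interest mask
#'
#' Binary mask on the same spatial grid as the series it annotates.
#' Labels follow the study design: an arterial ROI drives the AIF, lesion
#' and normal-appearing ROIs feed the parameter summaries.
#'
#' @slot voxels 3D logical array with at least one TRUE voxel.
#' @slot label one of "artery", "lesion", "normal".
#' @slot zone one of "PZ", "TZ", "none" (transition and central zones are
#'   merged into "TZ").
#'
#' @export
setClass("RoiMask",
  representation(voxels = "array", label = "character", zone = "character"),
  prototype(zone = "none")
)

setValidity("RoiMask", function(object) {
  msg <- NULL
  if (length(dim(object@voxels)) != 3L || !is.logical(object@voxels))
    msg <- c(msg, "voxels must be a 3D logical array")
  else if (!any(object@voxels)) msg <- c(msg, "mask contains no voxels")
  if (!object@label %in% c("artery", "lesion", "normal"))
    msg <- c(msg, "label must be one of artery/lesion/normal")
  if (!object@zone %in% c("PZ", "TZ", "none"))
    msg <- c(msg, "zone must be one of PZ/TZ/none")
  if (is.null(msg)) TRUE else msg
})

#' @param voxels 3D array; nonzero entries become TRUE.
#' @param label ROI label: "artery", "lesion" or "normal".
#' @param zone prostate zone label: "PZ", "TZ" or "none".
#' @rdname RoiMask-class
#' @export
RoiMask <- function(voxels, label, zone = "none") {
  v <- voxels != 0
  v[is.na(v)] <- FALSE
  dim(v) <- dim(voxels)
  new("RoiMask", voxels = v, label = label, zone = zone)
}

#' ParameterMap: a 3D map of one fitted parameter with validity mask
#'
#' Holds one named parameter volume together with a logical validity mask.
#' A voxel is valid only when the fit converged and the value lies inside
#' that parameter's physiologically credible range (see
#' [parameterRanges()]); on disk, invalid voxels are encoded as NaN.
#'
#' @slot parameter canonical parameter key (see [parameterRanges()]).
#' @slot values 3D numeric array.
#' @slot unit unit-of-measure string.
#' @slot valid 3D logical array, same shape as `values`.
#'
#' @export
setClass("ParameterMap",
  representation(parameter = "character", values = "array",
                 unit = "character", valid = "array")
)

setValidity("ParameterMap", function(object) {
  msg <- NULL
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (!is.logical(object@valid) ||
      !identical(dim(object@valid), dim(object@values)))
    msg <- c(msg, "valid must be a logical array matching values")
  if (any(object@valid & !is.finite(object@values)))
    msg <- c(msg, "valid voxels must hold finite values")
  if (is.null(msg)) TRUE else msg
})

#' @param parameter canonical parameter key.
#' @param values 3D numeric array.
#' @param unit unit-of-measure string.
#' @param valid 3D logical array (defaults to finite values).
#' @rdname ParameterMap-class
#' @export
ParameterMap <- function(parameter, values, unit = "", valid = NULL) {
  if (is.null(valid)) {
    valid <- is.finite(values)
    dim(valid) <- dim(values)
  }
  new("ParameterMap", parameter = parameter, values = values, unit = unit,
      valid = valid)
}

#' Aif: an arterial input function curve
#'
#' Mean contrast-agent concentration over an arterial ROI, one value per
#' dynamic, with the detected bolus-arrival frame. Used unscaled as the
#' plasma input driving tissue kinetics (no amplitude correction).
#'
#' @slot values numeric concentration curve, length = number of dynamics.
#' @slot arrivalFrame 1-based frame index of bolus arrival.
#' @slot sourceVoxelCount number of arterial voxels averaged.
#' @slot dtSeconds frame spacing in seconds.
#'
#' @export
setClass("Aif",
  representation(values = "numeric", arrivalFrame = "integer",
                 sourceVoxelCount = "integer", dtSeconds = "numeric")
)

setValidity("Aif", function(object) {
  msg <- NULL
  if (length(object@values) < 3L) msg <- c(msg, "AIF needs >= 3 frames")
  if (length(object@arrivalFrame) != 1L || object@arrivalFrame < 1L ||
      object@arrivalFrame > length(object@values))
    msg <- c(msg, "arrivalFrame out of range")
  if (object@sourceVoxelCount < 1L)
    msg <- c(msg, "sourceVoxelCount must be >= 1")
  if (object@dtSeconds <= 0) msg <- c(msg, "dtSeconds must be positive")
  if (is.null(msg)) TRUE else msg
})

#' @param values numeric concentration curve.
#' @param arrivalFrame 1-based arrival frame index.
#' @param sourceVoxelCount number of voxels averaged.
#' @param dtSeconds frame spacing in seconds.
#' @rdname Aif-class
#' @export
Aif <- function(values, arrivalFrame, sourceVoxelCount = 1L,
                dtSeconds = 1.695) {
  new("Aif", values = as.numeric(values),
      arrivalFrame = as.integer(arrivalFrame),
      sourceVoxelCount = as.integer(sourceVoxelCount),
      dtSeconds = as.numeric(dtSeconds))
}
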