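#' @include AllClasses.R
NULL

#' Accessors for ultraDCE data objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an ultraDCE object.
#' @return `voxelData()` the underlying array; `dtSeconds()` the frame
#'   spacing in seconds; `nDynamics()` the frame count; `arrivalFrame()`
#'   the 1-based bolus-arrival index; `validMask()` the logical validity
#'   array; `parameterName()`/`parameterUnit()` the map's key and unit;
#'   `roiLabel()`/`roiZone()` the mask labels; `aifValues()` the AIF curve.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("dtSeconds", function(x) standardGeneric("dtSeconds"))
#' @rdname accessors
#' @export
setGeneric("nDynamics", function(x) standardGeneric("nDynamics"))
#' @rdname accessors
#' @export
setGeneric("arrivalFrame", function(x) standardGeneric("arrivalFrame"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("parameterName", function(x) standardGeneric("parameterName"))
#' @rdname accessors
#' @export
setGeneric("parameterUnit", function(x) standardGeneric("parameterUnit"))
#' @rdname accessors
#' @export
setGeneric("roiLabel", function(x) standardGeneric("roiLabel"))
#' @rdname accessors
#' @export
setGeneric("roiZone", function(x) standardGeneric("roiZone"))
#' @rdname accessors
#' @export
setGeneric("aifValues", function(x) standardGeneric("aifValues"))

#' @rdname accessors
setMethod("voxelData", "DynamicSeries", function(x) x@voxels)
#' @rdname accessors
setMethod("voxelData", "ConcentrationSeries", function(x) x@voxels)
#' @rdname accessors
setMethod("voxelData", "RoiMask", function(x) x@voxels)
#' @rdname accessors
setMethod("voxelData", "ParameterMap", function(x) x@values)

#' @rdname accessors
setMethod("dtSeconds", "DynamicSeries", function(x) x@dtSeconds)
#' @rdname accessors
setMethod("dtSeconds", "ConcentrationSeries", function(x) x@dtSeconds)
#' @rdname accessors
setMethod("dtSeconds", "Aif", function(x) x@dtSeconds)

#' @rdname accessors
setMethod("nDynamics", "DynamicSeries", function(x) dim(x@voxels)[4])
#' @rdname accessors
setMethod("nDynamics", "ConcentrationSeries", function(x) dim(x@voxels)[4])
#' @rdname accessors
setMethod("nDynamics", "Aif", function(x) length(x@values))

#' @rdname accessors
setMethod("arrivalFrame", "ConcentrationSeries", function(x) x@arrivalFrame)
#' @rdname accessors
setMethod("arrivalFrame", "Aif", function(x) x@arrivalFrame)

#' @rdname accessors
setMethod("validMask", "ConcentrationSeries", function(x) x@valid)
#' @rdname accessors
setMethod("validMask", "ParameterMap", function(x) x@valid)

#' @rdname accessors
setMethod("parameterName", "ParameterMap", function(x) x@parameter)
#' @rdname accessors
setMethod("parameterUnit", "ParameterMap", function(x) x@unit)

#' @rdname accessors
setMethod("roiLabel", "RoiMask", function(x) x@label)
#' @rdname accessors
setMethod("roiZone", "RoiMask", function(x) x@zone)

#' @rdname accessors
setMethod("aifValues", "Aif", function(x) x@values)

setMethod("show", "DynamicSeries", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("DynamicSeries: %d x %d x %d voxels, %d dynamics @ %.4g s (%.1f s total)\n",
              d[1], d[2], d[3], d[4], object@dtSeconds,
              (d[4] - 1) * object@dtSeconds))
})

setMethod("show", "ConcentrationSeries", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ConcentrationSeries: %d x %d x %d voxels, %d dynamics @ %.4g s\n",
              d[1], d[2], d[3], d[4], object@dtSeconds))
  cat(sprintf("  arrival frame: %d; %d/%d voxels with usable baseline\n",
              object@arrivalFrame, sum(object@valid), prod(d[1:3])))
})

setMethod("show", "RoiMask", function(object) {
  cat(sprintf("RoiMask '%s' (zone %s): %d voxels\n", object@label,
              object@zone, sum(object@voxels)))
})

setMethod("show", "ParameterMap", function(object) {
  nv <- sum(object@valid)
  rng <- if (nv > 0) range(object@values[object@valid]) else c(NA, NA)
  cat(sprintf("ParameterMap '%s' [%s]: %d/%d valid voxels, range %.4g..%.4g\n",
              object@parameter, object@unit, nv, length(object@valid),
              rng[1], rng[2]))
})

setMethod("show", "Aif", function(object) {
  cat(sprintf("Aif: %d frames @ %.4g s, arrival frame %d, peak %.3g (%d source voxels)\n",
              length(object@values), object@dtSeconds, object@arrivalFrame,
              max(object@values), object@sourceVoxelCount))
})
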