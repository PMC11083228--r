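#' @include AllClasses.R utils.R
NULL

#' Read a 4D dynamic series from NIfTI
#'
#' Reads a 4D NIfTI volume into a [DynamicSeries-class]. The frame spacing
#' is taken from the header's 4th pixdim entry unless `dtOverride` is
#' given; a header without usable timing and no override is a
#' configuration error.
#'
#' @param path path to a 4D NIfTI file.
#' @param dtOverride frame spacing in seconds, overriding the header.
#' @return a [DynamicSeries-class].
#' @export
readDynamicSeries <- function(path, dtOverride = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    .dceError("dceDimensionError",
              sprintf("expected a 4D series, got %dD: %s", length(d), path))
  pd <- RNifti::pixdim(img)
  # temporal spacing counts as present only when the header also declares
  # time units (xyzt_units bits 3-5); RNifti normalizes absent pixdims to 1
  timeUnits <- bitwAnd(RNifti::niftiHeader(img)$xyzt_units, 56L)
  dt <- if (!is.null(dtOverride)) as.numeric(dtOverride)
        else if (timeUnits != 0L && length(pd) >= 4L && is.finite(pd[4]) &&
                 pd[4] > 0) pd[4]
        else .dceError("dceConfigError",
                       "no frame timing in header and no dtOverride given")
  spacing <- if (length(pd) >= 3L && all(pd[1:3] > 0)) pd[1:3] else c(1, 1, 1)
  DynamicSeries(array(as.numeric(img), dim = d), dtSeconds = dt,
                spacing = spacing)
}

#' Write a dynamic series to NIfTI
#'
#' Voxel values are stored as doubles and the frame spacing in the header's
#' temporal pixdim, so `readDynamicSeries(writeDynamicSeries(x))` is the
#' identity on both the array and the grid.
#'
#' @param series a [DynamicSeries-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeDynamicSeries <- function(series, path) {
  stopifnot(is(series, "DynamicSeries"))
  img <- RNifti::asNifti(series@voxels)
  RNifti::pixdim(img) <- c(series@spacing, series@dtSeconds)
  img$xyzt_units <- 10L  # mm + seconds
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a binary ROI mask from NIfTI
#'
#' Reads a 3D volume, checks it lives on the same spatial grid as the
#' series it annotates, and binarizes it (any nonzero voxel becomes TRUE).
#'
#' @param path path to a 3D NIfTI mask.
#' @param series the [DynamicSeries-class] or [ConcentrationSeries-class]
#'   the mask annotates.
#' @param label ROI label: "artery", "lesion" or "normal".
#' @param zone prostate zone: "PZ", "TZ" or "none".
#' @return a [RoiMask-class].
#' @export
readRoiMask <- function(path, series, label, zone = "none") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    .dceError("dceDimensionError",
              sprintf("expected a 3D mask, got %dD: %s", length(d), path))
  if (!identical(as.integer(d), as.integer(dim(voxelData(series))[1:3])))
    .dceError("dceGeometryError",
              "mask grid does not match the series spatial grid")
  v <- array(as.numeric(img), dim = d)
  if (!any(v != 0, na.rm = TRUE))
    .dceError("dceEmptyRoiError", sprintf("mask is empty: %s", path))
  RoiMask(v, label = label, zone = zone)
}

#' Write a binary ROI mask to NIfTI
#'
#' @param mask a [RoiMask-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRoiMask <- function(mask, path) {
  stopifnot(is(mask, "RoiMask"))
  img <- RNifti::asNifti(array(as.numeric(mask@voxels),
                               dim = dim(mask@voxels)))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

.validCompanionPath <- function(path) {
  sub("\\.nii(\\.gz)?$", "_valid.nii\\1", path)
}

#' Write a parameter map (with its validity mask) to NIfTI
#'
#' Invalid voxels are written as NaN in the value volume — NaN is the
#' on-disk encoding of "outside the credible range" — and a companion
#' `*_valid` volume stores the mask explicitly.
#'
#' @param map a [ParameterMap-class].
#' @param path output path for the value volume; the validity volume goes
#'   to the same path with a `_valid` suffix.
#' @return `path`, invisibly.
#' @export
writeParameterMap <- function(map, path) {
  stopifnot(is(map, "ParameterMap"))
  vals <- map@values
  vals[!map@valid] <- NaN
  RNifti::writeNifti(RNifti::asNifti(vals), path, datatype = "double")
  vimg <- RNifti::asNifti(array(as.numeric(map@valid), dim = dim(map@valid)))
  RNifti::writeNifti(vimg, .validCompanionPath(path), datatype = "uint8")
  invisible(path)
}

#' Read a parameter map written by [writeParameterMap()]
#'
#' @param path path to the value volume.
#' @param parameter canonical parameter key.
#' @param unit unit string; defaults to the canonical unit for `parameter`.
#' @return a [ParameterMap-class].
#' @export
readParameterMap <- function(path, parameter, unit = NULL) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  vpath <- .validCompanionPath(path)
  valid <- if (file.exists(vpath)) {
    array(as.numeric(RNifti::readNifti(vpath)) != 0, dim = dim(vals))
  } else {
    v <- is.finite(vals); dim(v) <- dim(vals); v
  }
  if (is.null(unit)) unit <- .paramUnit(parameter)
  ParameterMap(parameter, vals, unit = unit, valid = valid)
}

#' Read a per-ROI metadata table
#'
#' Expects a CSV with columns patient_id, roi_id, roi_type (lesion|normal),
#' zone (PZ|TZ), pirads (1|3|4|5) and gg (neg|1|2|3|4, empty for normal
#' ROIs). Normal-appearing ROIs are assigned PI-RADS 1.
#'
#' @param path path to the CSV file.
#' @return data.frame with validated columns.
#' @export
readRoiMetadata <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "roi_id", "roi_type", "zone", "pirads", "gg")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    .dceError("dceConfigError",
              paste("metadata is missing columns:", paste(miss, collapse = ", ")))
  if (!all(tab$roi_type %in% c("lesion", "normal")))
    .dceError("dceConfigError", "roi_type must be lesion or normal")
  if (!all(tab$zone %in% c("PZ", "TZ")))
    .dceError("dceConfigError", "zone must be PZ or TZ")
  bad <- tab$roi_type == "normal" & tab$pirads != 1
  if (any(bad))
    .dceError("dceConfigError", "normal ROIs must carry pirads = 1")
  bad <- tab$roi_type == "lesion" & !tab$pirads %in% c(3, 4, 5)
  if (any(bad))
    .dceError("dceConfigError", "lesion ROIs must carry pirads in 3..5")
  tab$gg <- as.character(tab$gg)
  tab$gg[tab$roi_type == "normal"] <- NA_character_
  tab
}
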