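#' @include AllClasses.R utils.R
NULL

#' Summarize a parameter map over an ROI
#'
#' Mean and sample standard deviation (denominator n - 1) over the voxels
#' that are both inside the ROI and inside the map's validity mask —
#' masking happens before averaging. An ROI whose every voxel is outside
#' the credible range yields an empty summary (NA mean/sd, n_valid = 0),
#' which propagates rather than erroring: this mirrors the real event of
#' a lesion ROI with no voxels in the accepted PS range.
#'
#' @param map a [ParameterMap-class].
#' @param roi a [RoiMask-class] on the same grid.
#' @return one-row data.frame: parameter, mean, sd, n_valid, n_total,
#'   empty.
#' @export
summarizeRoi <- function(map, roi) {
  stopifnot(is(map, "ParameterMap"), is(roi, "RoiMask"))
  if (!identical(dim(map@values), dim(roi@voxels)))
    .dceError("dceGeometryError", "map and ROI grids differ")
  sel <- roi@voxels & map@valid
  nValid <- sum(sel)
  vals <- map@values[sel]
  data.frame(parameter = map@parameter,
             mean = if (nValid >= 1L) mean(vals) else NA_real_,
             sd = if (nValid >= 2L) stats::sd(vals) else
               if (nValid == 1L) 0 else NA_real_,
             n_valid = nValid, n_total = sum(roi@voxels),
             empty = nValid == 0L, stringsAsFactors = FALSE)
}

#' Assemble per-ROI summaries into a long cohort table
#'
#' Each record pairs ROI metadata (patient, ROI id/type, zone, PI-RADS,
#' grade group) with a data.frame of parameter summaries as produced by
#' [summarizeRoi()]. Rows with empty summaries are dropped and logged —
#' dropping one parameter never removes the ROI's other parameters — and
#' duplicate (roi, parameter) pairs are a consistency error. Normal ROIs
#' carry PI-RADS 1 and no grade group.
#'
#' @param records list; each element a list with fields `patient_id`,
#'   `roi_id`, `roi_type`, `zone`, `pirads`, `gg` and `summaries`
#'   (data.frame of [summarizeRoi()] rows).
#' @return long data.frame (one row per ROI x parameter) with a
#'   `dropped` attribute logging removed rows and their reason.
#' @export
assembleCohort <- function(records) {
  if (!length(records)) {
    out <- data.frame(patient_id = character(), roi_id = character(),
                      roi_type = character(), zone = character(),
                      pirads = integer(), gg = character(),
                      parameter = character(), mean = numeric(),
                      sd = numeric(), n_valid = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "dropped") <- out[0, c("roi_id", "parameter")]
    return(out)
  }
  rows <- do.call(rbind, lapply(records, function(r) {
    need <- c("patient_id", "roi_id", "roi_type", "zone", "pirads", "gg")
    if (!all(need %in% names(r)))
      .dceError("dceConfigError", "incomplete record labels")
    s <- r$summaries
    data.frame(patient_id = r$patient_id, roi_id = r$roi_id,
               roi_type = r$roi_type, zone = r$zone,
               pirads = as.integer(r$pirads),
               gg = if (is.null(r$gg) || is.na(r$gg)) NA_character_
                    else as.character(r$gg),
               parameter = s$parameter, mean = s$mean, sd = s$sd,
               n_valid = s$n_valid, empty = s$empty,
               stringsAsFactors = FALSE)
  }))
  key <- paste(rows$roi_id, rows$parameter)
  if (anyDuplicated(key))
    .dceError("dceConsistencyError",
              "duplicate (roi, parameter) rows in cohort records")
  drop <- rows$empty | !is.finite(rows$mean)
  dropped <- rows[drop, c("roi_id", "parameter")]
  if (nrow(dropped)) dropped$reason <- "no valid voxels"
  out <- rows[!drop, setdiff(names(rows), "empty"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
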