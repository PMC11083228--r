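#' @include AllClasses.R utils.R prep.R kinetics.R emm.R roi.R stats.R
NULL

#' Default analysis configuration
#'
#' Every threshold surfaced here defaults to the study's stated value:
#' scale constant R = 1, a 2-minute analysis window, the combined
#' 120-s-or-to-peak uptake weighting, BH false-discovery level 0.05, and
#' biexponential starts (0.2, 0.2, 4).
#'
#' @param R signal-to-concentration scale constant.
#' @param windowS analysis window from arrival, seconds.
#' @param weightPolicy EMM uptake weighting, see [buildWeights()].
#' @param q BH false-discovery level.
#' @param fitT0 fit the 2CU bolus delay per voxel?
#' @param var.equal pooled-variance t-tests instead of Welch?
#' @param start2cu biexponential starting estimates.
#' @param seed RNG seed recorded in run manifests.
#' @return named list of class "DceConfig".
#' @export
dceConfig <- function(R = 1, windowS = 120, weightPolicy = "max120_peak",
                      q = 0.05, fitT0 = FALSE, var.equal = FALSE,
                      start2cu = c(alphaPlus = 0.2, alphaMinus = 0.2,
                                   betaMinus = 4),
                      seed = NULL) {
  structure(list(R = R, windowS = windowS, weightPolicy = weightPolicy,
                 q = q, fitT0 = fitT0, var.equal = var.equal,
                 start2cu = start2cu, seed = seed), class = "DceConfig")
}

#' Run the full single-patient pipeline
#'
#' Bolus preparation (arrival detection on the raw arterial mean curve,
#' baseline, concentration conversion, AIF extraction), voxelwise 2CU and
#' EMM fitting over the union of the tissue ROIs, and per-ROI
#' summarization with validity masking. Missing inputs fail hard;
#' per-voxel and per-ROI problems fail soft and are logged in the
#' manifest. Deterministic given the inputs and config.
#'
#' @param series a [DynamicSeries-class].
#' @param arteryMask arterial [RoiMask-class].
#' @param roiMasks named list of tissue [RoiMask-class] objects.
#' @param config a [dceConfig()].
#' @return list with `maps` (named [ParameterMap-class] list, 2CU + EMM +
#'   ttp), `summaries` (long data.frame of per-ROI summaries), `aif`,
#'   `arrivalFrame`, `manifest` (drops and settings).
#' @export
runPatient <- function(series, arteryMask, roiMasks, config = dceConfig()) {
  if (missing(arteryMask) || is.null(arteryMask))
    .dceError("dcePrepError", "artery mask is required")
  stopifnot(is(series, "DynamicSeries"), is(arteryMask, "RoiMask"))
  d <- dim(series@voxels)
  m <- matrix(series@voxels, nrow = prod(d[1:3]), ncol = d[4])
  arteryCurve <- colMeans(m[as.vector(arteryMask@voxels), , drop = FALSE])
  arrival <- detectArrival(arteryCurve)
  s0 <- computeBaseline(series, arrival)
  conc <- toConcentration(series, s0, R = config$R, arrivalFrame = arrival)
  aif <- extractAif(conc, arteryMask)
  tissue <- Reduce("|", lapply(roiMasks, voxelData))
  maps <- c(fitTwoCUVolume(conc, aif, mask = tissue,
                           windowS = config$windowS, fitT0 = config$fitT0,
                           start = config$start2cu),
            fitEmmVolume(conc, mask = tissue, windowS = config$windowS,
                         policy = config$weightPolicy))
  recs <- lapply(names(roiMasks), function(nm) {
    roi <- roiMasks[[nm]]
    do.call(rbind, lapply(maps, summarizeRoi, roi = roi)) |>
      transform(roi_id = nm, roi_type = roi@label, zone = roi@zone)
  })
  summaries <- do.call(rbind, recs)
  rownames(summaries) <- NULL
  dropped <- summaries[summaries$empty, c("roi_id", "parameter")]
  list(maps = maps, summaries = summaries, aif = aif,
       arrivalFrame = arrival,
       manifest = list(config = config, arrivalFrame = arrival,
                       dropped = dropped))
}

#' Run the cohort-level statistical analyses
#'
#' Thin orchestration over [runCohortStats()]: takes an assembled long
#' cohort table (from [assembleCohort()] over per-patient runs, or the
#' [makeCohort()] fast path) and emits the four analysis tables with BH
#' flags plus a manifest of skipped analyses.
#'
#' @param table long cohort table.
#' @param config a [dceConfig()].
#' @return see [runCohortStats()].
#' @export
runCohort <- function(table, config = dceConfig()) {
  if (length(unique(table$patient_id)) < 2L)
    .dceError("dceInsufficientDataError", "need >= 2 patients")
  runCohortStats(table, q = config$q, var.equal = config$var.equal)
}

#' Cohort exclusion accounting
#'
#' Screened count minus the enumerated exclusion counts; a negative
#' remainder is an accounting error. (In the motivating study, 337
#' screened minus 144 + 141 + 5 + 22 exclusions left 25 analyzed.)
#'
#' @param screened number screened.
#' @param exclusions vector of exclusion counts.
#' @return remaining count.
#' @export
applyExclusions <- function(screened, exclusions) {
  if (any(exclusions < 0) || screened < 0)
    .dceError("dceAccountingError", "counts must be nonnegative")
  remaining <- screened - sum(exclusions)
  if (remaining < 0)
    .dceError("dceAccountingError", "exclusions exceed the screened count")
  remaining
}
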