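#' @include AllClasses.R utils.R kinetics.R emm.R prep.R
NULL

#' Specify a synthetic arterial input function
#'
#' Stand-in for the measured iliac-artery input. The default is a
#' gamma-variate bolus \eqn{a\,(t - t_a)^b e^{-(t - t_a)/c}} for
#' \eqn{t > t_a} (zero before), normalized so its maximum equals
#' `peakAmplitude`, with an optional slow recirculation plateau at 10% of
#' the peak. "boxcar" and "impulse" shapes are provided for analytic
#' cross-checks; the impulse has unit area under the trapezoidal rule on
#' the minute axis.
#'
#' @param model "gamma_variate", "boxcar" or "impulse".
#' @param arrivalS bolus arrival time in seconds.
#' @param peakAmplitude peak concentration (unitless; enhancement scale).
#' @param shape gamma-variate shape b (> 0).
#' @param scaleS gamma-variate scale c in seconds (> 0); time to peak
#'   after arrival is `shape * scaleS`.
#' @param recirculation add the recirculation plateau?
#' @param durationS boxcar width in seconds.
#' @return list of class "AifSpec".
#' @export
aifSpec <- function(model = c("gamma_variate", "boxcar", "impulse"),
                    arrivalS = 25, peakAmplitude = 5, shape = 3,
                    scaleS = 3.6, recirculation = TRUE, durationS = 30) {
  model <- match.arg(model)
  if (shape <= 0 || scaleS <= 0 || peakAmplitude <= 0 || durationS < 0)
    .dceError("dceDomainError", "AIF shape parameters must be positive")
  structure(list(model = model, arrivalS = arrivalS,
                 peakAmplitude = peakAmplitude, shape = shape,
                 scaleS = scaleS, recirculation = recirculation,
                 durationS = durationS), class = "AifSpec")
}

#' Generate a synthetic AIF on an acquisition grid
#'
#' @param spec an [aifSpec()].
#' @param nDynamics number of frames.
#' @param dtSeconds frame spacing in seconds.
#' @return an [Aif-class] (deterministic; no noise).
#' @export
makeAif <- function(spec, nDynamics, dtSeconds) {
  stopifnot(inherits(spec, "AifSpec"))
  tS <- (seq_len(nDynamics) - 1) * dtSeconds
  tau <- tS - spec$arrivalS
  arrival <- max(4L, which(tau >= 0)[1])
  values <- switch(spec$model,
    impulse = {
      v <- numeric(nDynamics)
      # unit area under the trapezoidal rule on the minute axis (interior
      # samples carry weight dt, the first/last only dt/2)
      v[arrival] <- (if (arrival %in% c(1L, nDynamics)) 2 else 1) /
        (dtSeconds / 60)
      v
    },
    boxcar = ifelse(tau >= 0 & tau <= spec$durationS, spec$peakAmplitude, 0),
    gamma_variate = {
      tp <- spec$shape * spec$scaleS
      v <- ifelse(tau > 0,
                  spec$peakAmplitude * (tau / tp)^spec$shape *
                    exp(spec$shape * (1 - tau / tp)), 0)
      if (spec$recirculation)
        v <- v + ifelse(tau > 0,
                        0.1 * spec$peakAmplitude * (1 - exp(-tau / 30)), 0)
      v
    })
  Aif(values, arrivalFrame = arrival, sourceVoxelCount = 1L,
      dtSeconds = dtSeconds)
}

#' Simulate one voxel's signal curve from a known truth model
#'
#' Generates the concentration curve from the chosen forward model (2CU
#' physiological parameters driven by the supplied AIF, or one of the two
#' empirical models with onset at the AIF arrival frame), inverts the
#' signal equation \eqn{S = S_0 (1 + C/R)} with \eqn{R = 1}, and adds
#' seeded Gaussian noise on the signal. EMM time parameters are in
#' dynamics relative to arrival.
#'
#' @param model "2cu", "exp_emm" or "sigmoid_emm".
#' @param params named truth parameters: `vp`, `ps`, `fp` for 2CU;
#'   `A`, `alpha`, `t0` for the exponential; `A0`, `A1`, `A2` for the
#'   sigmoid.
#' @param aif an [Aif-class] driving (2CU) or timing (EMM) the curve.
#' @param s0 baseline signal level.
#' @param noiseSd Gaussian noise standard deviation as a fraction of `s0`.
#' @param seed RNG seed (required when `noiseSd > 0` for
#'   reproducibility; `NULL` leaves the RNG state alone).
#' @return numeric signal curve over all frames.
#' @export
simulateVoxel <- function(model = c("2cu", "exp_emm", "sigmoid_emm"),
                          params, aif, s0 = 100, noiseSd = 0, seed = NULL) {
  model <- match.arg(model)
  stopifnot(is(aif, "Aif"))
  n <- length(aif@values)
  timesMin <- (seq_len(n) - 1) * aif@dtSeconds / 60
  conc <- switch(model,
    "2cu" = forwardTwoCU(physioToBiexp(params), aif@values, timesMin),
    exp_emm = expEmmCurve(c(A = params[["A"]], alpha = params[["alpha"]],
                            t0 = aif@arrivalFrame - 1 + params[["t0"]]),
                          seq_len(n) - 1),
    sigmoid_emm = sigmoidEmmCurve(c(A0 = params[["A0"]],
                                    A1 = aif@arrivalFrame - 1 + params[["A1"]],
                                    A2 = params[["A2"]]),
                                  seq_len(n) - 1))
  sig <- s0 * (1 + conc)
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    sig <- sig + stats::rnorm(n, 0, noiseSd * s0)
  }
  sig
}

.boxIndices <- function(box, d) {
  stopifnot(all(c("x", "y", "z") %in% names(box)))
  arr <- array(FALSE, d)
  arr[box$x, box$y, box$z] <- TRUE
  arr
}

#' Specify a digital reference object phantom
#'
#' A small 4D phantom emulating the study acquisition (default 1.695 s
#' frame spacing, 150 dynamics): an arterial region carrying the AIF and
#' tissue regions generated from known truth models, with seeded Gaussian
#' (or Rician) noise on the signal.
#'
#' @param dim spatial grid, length 3.
#' @param dtSeconds frame spacing in seconds.
#' @param nDynamics number of frames.
#' @param s0 baseline signal.
#' @param noiseSd noise SD as a fraction of `s0`.
#' @param noiseModel "gaussian" or "rician".
#' @param aif an [aifSpec()].
#' @param arteryBox list(x=, y=, z=) of index vectors for the artery.
#' @param regions list of regions, each list(name=, label=("lesion" or
#'   "normal"), zone=, model=, params=, box=list(x=,y=,z=)).
#' @param seed RNG seed (mandatory).
#' @return list of class "PhantomSpec".
#' @export
phantomSpec <- function(dim = c(16, 16, 4), dtSeconds = 1.695,
                        nDynamics = 150, s0 = 100, noiseSd = 0.01,
                        noiseModel = c("gaussian", "rician"),
                        aif = aifSpec(),
                        arteryBox = list(x = 1:3, y = 1:3, z = seq_len(dim[3])),
                        regions = list(
                          list(name = "lesion", label = "lesion", zone = "PZ",
                               model = "2cu",
                               params = c(vp = 0.2, ps = 0.4, fp = 0.4),
                               box = list(x = 6:10, y = 6:10,
                                          z = seq_len(dim[3]))),
                          list(name = "normal", label = "normal", zone = "PZ",
                               model = "2cu",
                               params = c(vp = 0.1, ps = 0.1, fp = 0.2),
                               box = list(x = 12:15, y = 12:15,
                                          z = seq_len(dim[3])))),
                        seed) {
  if (missing(seed)) .dceError("dceConfigError", "phantom seed is mandatory")
  structure(list(dim = dim, dtSeconds = dtSeconds, nDynamics = nDynamics,
                 s0 = s0, noiseSd = noiseSd,
                 noiseModel = match.arg(noiseModel), aif = aif,
                 arteryBox = arteryBox, regions = regions, seed = seed),
            class = "PhantomSpec")
}

#' Build a digital reference object phantom
#'
#' @param spec a [phantomSpec()].
#' @return list with `series` ([DynamicSeries-class]), `masks` (named list
#'   of [RoiMask-class], artery first), `aif` (noise-free truth
#'   [Aif-class]), `truth` (data.frame of region truth parameters) and
#'   `arrivalFrame`.
#' @export
makePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  set.seed(spec$seed)
  d <- spec$dim
  n <- spec$nDynamics
  aifTruth <- makeAif(spec$aif, n, spec$dtSeconds)
  boxes <- c(list(.boxIndices(spec$arteryBox, d)),
             lapply(spec$regions, function(r) .boxIndices(r$box, d)))
  overlap <- Reduce("+", lapply(boxes, function(b) b * 1L))
  if (any(overlap > 1L))
    .dceError("dceGeometryError", "phantom regions overlap")
  sig <- array(spec$s0, dim = c(d, n))
  flat <- matrix(sig, nrow = prod(d), ncol = n)
  flat[which(boxes[[1]]), ] <- rep(spec$s0 * (1 + aifTruth@values),
                                   each = sum(boxes[[1]]))
  for (i in seq_along(spec$regions)) {
    r <- spec$regions[[i]]
    curve <- simulateVoxel(r$model, r$params, aifTruth, s0 = spec$s0,
                           noiseSd = 0)
    flat[which(boxes[[i + 1L]]), ] <- rep(curve, each = sum(boxes[[i + 1L]]))
  }
  if (spec$noiseSd > 0) {
    sd <- spec$noiseSd * spec$s0
    if (spec$noiseModel == "gaussian") {
      flat <- flat + stats::rnorm(length(flat), 0, sd)
    } else {
      flat <- sqrt((flat + stats::rnorm(length(flat), 0, sd))^2 +
                     stats::rnorm(length(flat), 0, sd)^2)
    }
  }
  series <- DynamicSeries(array(flat, dim = c(d, n)),
                          dtSeconds = spec$dtSeconds)
  masks <- c(list(artery = RoiMask(boxes[[1]] * 1, "artery")),
             stats::setNames(lapply(seq_along(spec$regions), function(i) {
               RoiMask(boxes[[i + 1L]] * 1, spec$regions[[i]]$label,
                       spec$regions[[i]]$zone)
             }), vapply(spec$regions, `[[`, "", "name")))
  truth <- do.call(rbind, lapply(spec$regions, function(r) {
    data.frame(region = r$name, model = r$model,
               parameter = names(r$params), value = as.numeric(r$params),
               stringsAsFactors = FALSE)
  }))
  list(series = series, masks = masks, aif = aifTruth, truth = truth,
       arrivalFrame = aifTruth@arrivalFrame)
}

# Study-scale parameter levels used as simulation defaults: baselines are
# normal-appearing peripheral-zone magnitudes; zone shifts and the
# monotone severity effects (in within-group SD units per level) emulate
# the qualitative cohort structure (fast early enhancement rises with
# lesion severity; transit times and sigmoid widths fall; vp, PS and
# Ktrans carry no effect).
.cohortBaselines <- c(vp = 1.76, ps = 0.108, fp = 1.36, mttp = 1.44,
                      tc = 1.53, e = 0.086, ktrans = 0.094, alpha = 0.072,
                      a1_minus_t0 = 16.7, a2 = 15.1, ttp = 60)
.cohortZoneShifts <- c(vp = 0, ps = 0, fp = 1.0, mttp = 0, tc = 0,
                       e = -0.6, ktrans = 0, alpha = 1.3,
                       a1_minus_t0 = -0.6, a2 = -0.6, ttp = 0)
.cohortEffects <- c(vp = 0, ps = 0, fp = 0.8, mttp = -0.8, tc = -0.8,
                    e = 0.8, ktrans = 0, alpha = 0.8, a1_minus_t0 = -0.8,
                    a2 = -0.8, ttp = -0.8)

#' Specify a synthetic cohort
#'
#' Emulates the study composition: 25 patients with 35 PI-RADS >= 3
#' lesions (16 patients with one lesion, 8 with two, 1 with three), of
#' which 4 are PI-RADS 3, 21 PI-RADS 4 and 10 PI-RADS 5; 29 peripheral-
#' and 6 transition-zone; biopsy grade groups 11 negative and 6/9/5/4 for
#' GG1-GG4. Every lesion is paired with a normal-appearing ROI in the
#' same zone (PI-RADS 1). ROI-level parameter means are drawn as
#' baseline + zone shift + monotone severity effect + Gaussian noise,
#' with effects expressed in within-group SD units per severity level.
#'
#' @param nPatients number of patients.
#' @param lesionsPerPatient named counts: how many patients carry 1, 2,
#'   ... lesions (must sum to `nPatients`).
#' @param piradsCounts named lesion counts for categories "3", "4", "5".
#' @param zoneCounts named lesion counts for "PZ", "TZ".
#' @param ggCounts named biopsy counts for "neg", "1".."4".
#' @param baselines named per-parameter baseline means.
#' @param zoneShifts named TZ-vs-PZ shifts in SD units.
#' @param effectSizes named monotone shifts per severity level, SD units.
#' @param noiseCV within-group SD as a fraction of the baseline mean.
#' @param ggCoupling SD of the jitter used when rank-matching grade
#'   groups to PI-RADS categories (larger = weaker coupling).
#' @param seed RNG seed (mandatory).
#' @return list of class "CohortSpec".
#' @export
cohortSpec <- function(nPatients = 25,
                       lesionsPerPatient = c(`1` = 16, `2` = 8, `3` = 1),
                       piradsCounts = c(`3` = 4, `4` = 21, `5` = 10),
                       zoneCounts = c(PZ = 29, TZ = 6),
                       ggCounts = c(neg = 11, `1` = 6, `2` = 9, `3` = 5,
                                    `4` = 4),
                       baselines = .cohortBaselines,
                       zoneShifts = .cohortZoneShifts,
                       effectSizes = .cohortEffects,
                       noiseCV = 0.4, ggCoupling = 1.0, seed) {
  if (missing(seed)) .dceError("dceConfigError", "cohort seed is mandatory")
  nLesions <- sum(piradsCounts)
  if (sum(lesionsPerPatient) != nPatients)
    .dceError("dceConfigError", "lesionsPerPatient must sum to nPatients")
  if (sum(as.integer(names(lesionsPerPatient)) * lesionsPerPatient) !=
      nLesions)
    .dceError("dceConfigError", "lesion counts inconsistent with piradsCounts")
  if (sum(zoneCounts) != nLesions || sum(ggCounts) != nLesions)
    .dceError("dceConfigError", "zone/gg counts must sum to the lesion count")
  structure(list(nPatients = nPatients,
                 lesionsPerPatient = lesionsPerPatient,
                 piradsCounts = piradsCounts, zoneCounts = zoneCounts,
                 ggCounts = ggCounts, baselines = baselines,
                 zoneShifts = zoneShifts, effectSizes = effectSizes,
                 noiseCV = noiseCV, ggCoupling = ggCoupling, seed = seed),
            class = "CohortSpec")
}

# Severity index driving the monotone effects: 0 for normal-appearing
# tissue; for lesions the mean of the PI-RADS step (1..3 for categories
# 3..5) and the scaled grade group (0..3 for neg..GG4).
.severity <- function(pirads, gg) {
  prIdx <- pirads - 2
  ggNum <- match(gg, c("neg", "1", "2", "3", "4")) - 1
  (prIdx + 0.75 * ggNum) / 2
}

#' Draw a synthetic cohort table (fast path)
#'
#' Generates the long cohort table directly from the effect model, with
#' no voxel data: statistics-level validation does not need images. Lesion
#' grade groups are coupled to PI-RADS categories by jittered rank
#' matching, so one latent severity axis produces monotone trends in both
#' factors while the marginal label counts match the specification
#' exactly. Reproducible given the spec seed.
#'
#' @param spec a [cohortSpec()].
#' @return long cohort data.frame (patient_id, roi_id, roi_type, zone,
#'   pirads, gg, parameter, mean), 2 ROIs (lesion + paired normal) per
#'   lesion x one row per analyzed parameter.
#' @export
makeCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  nLes <- sum(spec$piradsCounts)
  patientOf <- rep(seq_len(spec$nPatients),
                   rep(as.integer(names(spec$lesionsPerPatient)),
                       spec$lesionsPerPatient))[seq_len(nLes)]
  pirads <- sample(rep(as.integer(names(spec$piradsCounts)),
                       spec$piradsCounts))
  zone <- sample(rep(names(spec$zoneCounts), spec$zoneCounts))
  # Rank-match grade groups to jittered PI-RADS scores.
  ggPool <- rep(names(spec$ggCounts), spec$ggCounts)
  score <- pirads + stats::rnorm(nLes, 0, spec$ggCoupling)
  gg <- character(nLes)
  gg[order(score)] <- ggPool  # ggPool already ordered neg < 1 < ... < 4
  params <- names(spec$baselines)
  sds <- spec$noiseCV * abs(spec$baselines)
  rows <- vector("list", 2L * nLes)
  for (i in seq_len(nLes)) {
    sev <- .severity(pirads[i], gg[i])
    tzShift <- as.numeric(zone[i] == "TZ")
    lesionMeans <- spec$baselines + tzShift * spec$zoneShifts * sds +
      sev * spec$effectSizes * sds + stats::rnorm(length(params), 0, sds)
    normalMeans <- spec$baselines + tzShift * spec$zoneShifts * sds +
      stats::rnorm(length(params), 0, sds)
    rows[[2L * i - 1L]] <- data.frame(
      patient_id = sprintf("P%02d", patientOf[i]),
      roi_id = sprintf("L%02d", i), roi_type = "lesion", zone = zone[i],
      pirads = pirads[i], gg = gg[i], parameter = params,
      mean = as.numeric(lesionMeans), stringsAsFactors = FALSE)
    rows[[2L * i]] <- data.frame(
      patient_id = sprintf("P%02d", patientOf[i]),
      roi_id = sprintf("N%02d", i), roi_type = "normal", zone = zone[i],
      pirads = 1L, gg = NA_character_, parameter = params,
      mean = as.numeric(normalMeans), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
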