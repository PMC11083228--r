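#' @include utils.R
NULL

# A cohort table is long format: patient_id, roi_id, roi_type, zone,
# pirads, gg, parameter, mean. One ROI-level mean is the unit of analysis.

.paramRows <- function(table, parameter) {
  tab <- table[table$parameter == parameter & is.finite(table$mean), ,
               drop = FALSE]
  if (!nrow(tab))
    .dceError("dceInsufficientDataError",
              sprintf("no data for parameter '%s'", parameter))
  tab
}

# Zero-variance convention: identical constant groups are "no evidence of
# a difference" (p = 1, flagged) rather than a pipeline failure.
.safeTTest <- function(x, y, var.equal = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    .dceError("dceInsufficientDataError", "need >= 2 observations per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(list(p.value = if (mean(x) == mean(y)) 1 else 0,
                zeroVariance = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = var.equal)
  list(p.value = ht$p.value, zeroVariance = FALSE)
}

#' Zone comparison t-test on normal-appearing tissue
#'
#' Two-sample t-test (Welch by default) of ROI-level parameter means
#' between the radiologically normal-appearing peripheral and transition
#' zones.
#'
#' @param table long cohort table.
#' @param parameter canonical parameter key.
#' @param var.equal use the pooled-variance Student test instead of Welch.
#' @return list with `p.value`, `n` (per-zone counts), `zeroVariance`.
#' @export
zoneTTest <- function(table, parameter, var.equal = FALSE) {
  tab <- .paramRows(table, parameter)
  tab <- tab[tab$roi_type == "normal", , drop = FALSE]
  pz <- tab$mean[tab$zone == "PZ"]
  tz <- tab$mean[tab$zone == "TZ"]
  if (length(pz) < 2L || length(tz) < 2L)
    .dceError("dceInsufficientDataError", "a zone is absent or too small")
  res <- .safeTTest(pz, tz, var.equal = var.equal)
  c(res, list(n = c(PZ = length(pz), TZ = length(tz))))
}

#' Two-way ANOVA with zone and PI-RADS category as factors
#'
#' Main-effects linear model (no interaction) over all ROIs, with
#' normal-appearing tissue entering as PI-RADS 1, giving 4 category
#' levels. Because the design is heavily unbalanced, factor p-values use
#' Type II sums of squares (each factor adjusted for the other), one
#' p-value per factor.
#'
#' @param table long cohort table.
#' @param parameter canonical parameter key.
#' @return list with `p.zone`, `p.pirads`, `zeroVariance`.
#' @export
twowayAnova <- function(table, parameter) {
  tab <- .paramRows(table, parameter)
  zone <- factor(tab$zone, levels = c("PZ", "TZ"))
  pirads <- factor(tab$pirads, levels = c(1, 3, 4, 5))
  if (nlevels(droplevels(zone)) < 2L || nlevels(droplevels(pirads)) < 2L)
    .dceError("dceEstimabilityError",
              "both factors need >= 2 observed levels")
  if (stats::sd(tab$mean) == 0)
    return(list(p.zone = 1, p.pirads = 1, zeroVariance = TRUE))
  fit <- stats::lm(tab$mean ~ droplevels(zone) + droplevels(pirads))
  a2 <- car::Anova(fit, type = "II")
  pv <- a2[["Pr(>F)"]]
  list(p.zone = pv[1], p.pirads = pv[2], zeroVariance = FALSE)
}

#' Biopsy-outcome t-test in the peripheral zone
#'
#' Two-sample t-test of lesion ROI means between grade-group negative and
#' positive (GG >= 1) biopsy findings, peripheral zone only.
#'
#' @inheritParams zoneTTest
#' @return list with `p.value`, `n`, `zeroVariance`.
#' @export
biopsyTTest <- function(table, parameter, var.equal = FALSE) {
  tab <- .paramRows(table, parameter)
  tab <- tab[tab$roi_type == "lesion" & tab$zone == "PZ" & !is.na(tab$gg), ,
             drop = FALSE]
  neg <- tab$mean[tab$gg == "neg"]
  pos <- tab$mean[tab$gg != "neg"]
  if (length(neg) < 2L || length(pos) < 2L)
    .dceError("dceInsufficientDataError", "a biopsy class is absent")
  res <- .safeTTest(neg, pos, var.equal = var.equal)
  c(res, list(n = c(neg = length(neg), pos = length(pos))))
}

# Grade-group factor for the one-way analysis: normal-appearing ROIs and
# negative biopsies pool into "neg"; positive lesions keep their GG.
.ggGroups <- function(tab) {
  g <- ifelse(tab$roi_type == "normal" | tab$gg %in% "neg", "neg", tab$gg)
  factor(g, levels = c("neg", "1", "2", "3", "4"))
}

#' One-way ANOVA across grade groups in the peripheral zone
#'
#' Pools the radiologically normal-appearing ROIs into the GG-negative
#' category (5 levels: neg, GG1-GG4) and tests for any difference in
#' ROI-level means, peripheral zone only.
#'
#' @inheritParams zoneTTest
#' @return list with `p.value`, `groups` (level counts), `zeroVariance`.
#' @export
onewayAnovaGG <- function(table, parameter) {
  tab <- .paramRows(table, parameter)
  tab <- tab[tab$zone == "PZ", , drop = FALSE]
  g <- droplevels(.ggGroups(tab))
  counts <- base::table(g)
  if (sum(counts >= 2L) < 2L || nlevels(g) < 2L)
    .dceError("dceInsufficientDataError",
              "need >= 2 grade-group levels with >= 2 observations")
  if (stats::sd(tab$mean) == 0)
    return(list(p.value = 1, groups = counts, zeroVariance = TRUE))
  fit <- stats::aov(tab$mean ~ g)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  list(p.value = p, groups = counts, zeroVariance = FALSE)
}

#' Tukey HSD post hoc pairwise comparisons
#'
#' Tukey-Kramer adjusted pairwise p-values (valid for unequal group
#' sizes) for the grouping used by one of the omnibus ANOVAs. Intended
#' for parameters whose ANOVA was flagged significant.
#'
#' @param table long cohort table.
#' @param parameter canonical parameter key.
#' @param grouping "pirads" (all ROIs; normal = category 1) or "gg"
#'   (peripheral zone; normals pooled into "neg").
#' @return data.frame with contrast, diff, lwr, upr, p.adj.
#' @export
tukeyHsd <- function(table, parameter, grouping = c("pirads", "gg")) {
  grouping <- match.arg(grouping)
  tab <- .paramRows(table, parameter)
  if (grouping == "pirads") {
    g <- droplevels(factor(tab$pirads, levels = c(1, 3, 4, 5)))
  } else {
    tab <- tab[tab$zone == "PZ", , drop = FALSE]
    g <- droplevels(.ggGroups(tab))
  }
  if (nlevels(g) < 2L)
    .dceError("dceInsufficientDataError", "need >= 2 groups for Tukey HSD")
  fit <- stats::aov(tab$mean ~ g)
  th <- stats::TukeyHSD(fit)$g
  data.frame(contrast = rownames(th), diff = th[, "diff"],
             lwr = th[, "lwr"], upr = th[, "upr"],
             p.adj = th[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up correction
#'
#' Standard BH step-up over one family of p-values at false-discovery
#' level `q`. In the cohort analysis the family is the 33 ANOVA p-values:
#' 11 parameters x 2 factors from the two-way table plus 11 one-way
#' grade-group tests. The t-test families are reported uncorrected.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param q false-discovery level (default 0.05).
#' @return data.frame with p, p.adjusted (BH), significant flag.
#' @export
bhCorrect <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  adj <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, p.adjusted = adj, significant = !is.na(adj) & adj <= q)
}

#' Run the four cohort analyses for every analyzed parameter
#'
#' For each parameter: the normal-tissue zone t-test, the two-way
#' zone x PI-RADS ANOVA (Type II), the peripheral-zone biopsy t-test, and
#' the one-way grade-group ANOVA; then one BH correction across the
#' 22 + 11 = 33 ANOVA p-values, and Tukey HSD post hoc tables for the
#' parameters whose ANOVA factors are BH-significant. Analyses whose
#' preconditions fail (a missing level, too few observations) are skipped
#' and logged, never fatal.
#'
#' @param table long cohort table.
#' @param parameters parameter keys (default [analyzedParameters()]).
#' @param q BH false-discovery level.
#' @param var.equal use pooled-variance t-tests.
#' @return list with `zone` (t-test table), `twoway`, `gg` (ANOVA tables
#'   with BH-adjusted p and flags), `biopsy`, `tukey` (named list of post
#'   hoc tables), `skipped` (log of skipped analyses).
#' @export
runCohortStats <- function(table, parameters = analyzedParameters(),
                           q = 0.05, var.equal = FALSE) {
  skipped <- list()
  note <- function(analysis, parameter, cond) {
    skipped[[length(skipped) + 1L]] <<- data.frame(
      analysis = analysis, parameter = parameter,
      reason = conditionMessage(cond), stringsAsFactors = FALSE)
    NULL
  }
  zone <- do.call(rbind, lapply(parameters, function(pm) {
    r <- tryCatch(zoneTTest(table, pm, var.equal = var.equal),
                  dceError = function(e) note("zone_ttest", pm, e))
    if (is.null(r)) return(NULL)
    data.frame(parameter = pm, p = r$p.value, stringsAsFactors = FALSE)
  }))
  twoway <- do.call(rbind, lapply(parameters, function(pm) {
    r <- tryCatch(twowayAnova(table, pm),
                  dceError = function(e) note("twoway_anova", pm, e))
    if (is.null(r)) return(NULL)
    data.frame(parameter = pm, p.zone = r$p.zone, p.pirads = r$p.pirads,
               stringsAsFactors = FALSE)
  }))
  biopsy <- do.call(rbind, lapply(parameters, function(pm) {
    r <- tryCatch(biopsyTTest(table, pm, var.equal = var.equal),
                  dceError = function(e) note("biopsy_ttest", pm, e))
    if (is.null(r)) return(NULL)
    data.frame(parameter = pm, p = r$p.value, stringsAsFactors = FALSE)
  }))
  gg <- do.call(rbind, lapply(parameters, function(pm) {
    r <- tryCatch(onewayAnovaGG(table, pm),
                  dceError = function(e) note("oneway_anova_gg", pm, e))
    if (is.null(r)) return(NULL)
    data.frame(parameter = pm, p = r$p.value, stringsAsFactors = FALSE)
  }))

  # One BH family across all ANOVA p-values (two-way factors + one-way GG).
  fam <- c(if (!is.null(twoway)) twoway$p.zone,
           if (!is.null(twoway)) twoway$p.pirads,
           if (!is.null(gg)) gg$p)
  bh <- bhCorrect(fam, q = q)
  nTw <- if (is.null(twoway)) 0L else nrow(twoway)
  if (nTw) {
    twoway$p.zone.adj <- bh$p.adjusted[seq_len(nTw)]
    twoway$sig.zone <- bh$significant[seq_len(nTw)]
    twoway$p.pirads.adj <- bh$p.adjusted[nTw + seq_len(nTw)]
    twoway$sig.pirads <- bh$significant[nTw + seq_len(nTw)]
  }
  if (!is.null(gg)) {
    idx <- 2L * nTw + seq_len(nrow(gg))
    gg$p.adj <- bh$p.adjusted[idx]
    gg$sig <- bh$significant[idx]
  }

  tukey <- list()
  if (!is.null(twoway)) {
    for (pm in twoway$parameter[twoway$sig.pirads]) {
      tukey[[paste0(pm, ".pirads")]] <- tryCatch(
        tukeyHsd(table, pm, "pirads"),
        dceError = function(e) note("tukey_pirads", pm, e))
    }
  }
  if (!is.null(gg)) {
    for (pm in gg$parameter[gg$sig]) {
      tukey[[paste0(pm, ".gg")]] <- tryCatch(
        tukeyHsd(table, pm, "gg"),
        dceError = function(e) note("tukey_gg", pm, e))
    }
  }
  list(zone = zone, twoway = twoway, biopsy = biopsy, gg = gg,
       tukey = tukey, bhFamily = bh,
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
}
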