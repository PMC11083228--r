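# Minimal long-table builders for statistics-level tests.
normalTable <- function(pz, tz, parameter = "fp") {
  n <- length(pz) + length(tz)
  data.frame(patient_id = sprintf("P%02d", seq_len(n)),
             roi_id = sprintf("N%02d", seq_len(n)), roi_type = "normal",
             zone = rep(c("PZ", "TZ"), c(length(pz), length(tz))),
             pirads = 1L, gg = NA_character_, parameter = parameter,
             mean = c(pz, tz), stringsAsFactors = FALSE)
}

test_that("zone t-test handles identical and degenerate groups", {
  expect_equal(zoneTTest(normalTable(c(1, 2, 3), c(1, 2, 3)), "fp")$p.value,
               1)
  zv <- zoneTTest(normalTable(c(2, 2, 2), c(2, 2, 2)), "fp")
  expect_equal(zv$p.value, 1)
  expect_true(zv$zeroVariance)
  expect_error(zoneTTest(normalTable(c(1, 2), numeric(0)), "fp"),
               class = "dceInsufficientDataError")
})

test_that("zone t-test detects a large injected zone effect", {
  # effect of 3 SD with the study's 29 vs 6 split: near-certain detection
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    zoneTTest(normalTable(rnorm(29), rnorm(6, mean = 3)), "fp")$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("two-way ANOVA returns one Type II p per factor", {
  tab <- makeCohort(cohortSpec(seed = 31))
  r <- twowayAnova(tab, "fp")
  expect_true(r$p.zone >= 0 && r$p.zone <= 1)
  expect_true(r$p.pirads >= 0 && r$p.pirads <= 1)

  # all observations equal: both p = 1 with the zero-variance flag
  flat <- tab[tab$parameter == "fp", ]
  flat$mean <- 5
  r0 <- twowayAnova(flat, "fp")
  expect_equal(c(r0$p.zone, r0$p.pirads), c(1, 1))
  expect_true(r0$zeroVariance)
})

test_that("Type II equals Type I on a balanced two-way design", {
  set.seed(41)
  zones <- rep(c("PZ", "TZ"), each = 8)
  pirads <- rep(rep(c(1L, 3L, 4L, 5L), each = 2), 2)
  y <- rnorm(16) + 0.5 * (pirads == 5)
  tab <- data.frame(patient_id = sprintf("P%02d", 1:16),
                    roi_id = sprintf("R%02d", 1:16),
                    roi_type = ifelse(pirads == 1, "normal", "lesion"),
                    zone = zones, pirads = pirads, gg = NA_character_,
                    parameter = "fp", mean = y, stringsAsFactors = FALSE)
  r <- twowayAnova(tab, "fp")
  a1 <- anova(lm(y ~ factor(zones) + factor(pirads)))  # Type I (sequential)
  expect_equal(r$p.zone, a1[["Pr(>F)"]][1], tolerance = 1e-10)
  expect_equal(r$p.pirads, a1[["Pr(>F)"]][2], tolerance = 1e-10)
})

test_that("a pure PI-RADS effect does not leak into the zone factor", {
  reps <- 120
  pz <- vapply(1:reps, function(s) {
    spec <- cohortSpec(zoneShifts = ultraDCE:::.cohortZoneShifts * 0,
                       seed = 1000 + s)
    tab <- makeCohort(spec)
    r <- twowayAnova(tab, "fp")   # fp carries a PI-RADS effect, no zone
    c(r$p.zone, r$p.pirads)
  }, numeric(2))
  expect_gte(mean(pz[2, ] < 0.05), 0.9)      # PI-RADS effect detected
  rate <- mean(pz[1, ] < 0.05)               # zone stays near nominal
  expect_lt(rate, 0.05 + 2.5 * sqrt(0.05 * 0.95 / reps))
})

test_that("biopsy t-test compares GG-negative and positive PZ lesions", {
  tab <- makeCohort(cohortSpec(seed = 51))
  r <- biopsyTTest(tab, "fp")
  expect_true(r$p.value >= 0 && r$p.value <= 1)
  expect_equal(sum(r$n), 29)  # PZ lesions only

  # injected 2 SD effect at n = 11 vs 18: power above 80%
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    les <- data.frame(patient_id = sprintf("P%02d", 1:29),
                      roi_id = sprintf("L%02d", 1:29), roi_type = "lesion",
                      zone = "PZ",
                      pirads = 4L,
                      gg = rep(c("neg", "2"), c(11, 18)),
                      parameter = "fp",
                      mean = c(rnorm(11), rnorm(18, 2)),
                      stringsAsFactors = FALSE)
    biopsyTTest(les, "fp")$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("one-way GG ANOVA pools normals into the negative class", {
  tab <- makeCohort(cohortSpec(seed = 61))
  r <- onewayAnovaGG(tab, "fp")
  # 29 PZ normals + 11-ish PZ negative lesions pooled together
  expect_equal(sum(r$groups), sum(tab$parameter == "fp" & tab$zone == "PZ"))
  expect_gt(r$groups[["neg"]], 29)

  one <- tab[tab$parameter == "fp" & tab$roi_type == "normal" &
               tab$zone == "PZ", ]
  expect_error(onewayAnovaGG(one, "fp"),
               class = "dceInsufficientDataError")
})

test_that("Tukey HSD reduces to the pooled t-test for two groups", {
  set.seed(71)
  y <- c(rnorm(8), rnorm(6, 1))
  g <- rep(c("neg", "2"), c(8, 6))
  tab <- data.frame(patient_id = sprintf("P%02d", 1:14),
                    roi_id = sprintf("L%02d", 1:14), roi_type = "lesion",
                    zone = "PZ", pirads = 4L, gg = g, parameter = "fp",
                    mean = y, stringsAsFactors = FALSE)
  th <- tukeyHsd(tab, "fp", "gg")
  expect_equal(nrow(th), 1)
  pooled <- t.test(y ~ g, var.equal = TRUE)$p.value
  expect_equal(th$p.adj, pooled, tolerance = 1e-8)
})

test_that("Tukey HSD flags only contrasts involving the shifted group", {
  set.seed(81)
  y <- c(rnorm(12), rnorm(12), rnorm(12), rnorm(12, 4))
  g <- rep(c("neg", "1", "2", "3"), each = 12)
  tab <- data.frame(patient_id = sprintf("P%02d", 1:48),
                    roi_id = sprintf("L%02d", 1:48), roi_type = "lesion",
                    zone = "PZ", pirads = 4L, gg = g, parameter = "fp",
                    mean = y, stringsAsFactors = FALSE)
  th <- tukeyHsd(tab, "fp", "gg")
  hit3 <- grepl("3", th$contrast)
  expect_true(all(th$p.adj[hit3] < 0.001))
  expect_true(all(th$p.adj[!hit3] > 0.001))
  expect_gt(min(th$p.adj[!hit3]), max(th$p.adj[hit3]))
})

test_that("BH correction matches the brute-force step-up oracle", {
  expect_true(all(bhCorrect(c(0.01, 0.02, 0.03, 0.04))$significant))
  allOne <- bhCorrect(rep(1, 5))
  expect_false(any(allOne$significant))
  expect_true(all(allOne$p.adjusted == 1))
  single <- bhCorrect(0.04)
  expect_true(single$significant)
  expect_equal(single$p.adjusted, 0.04)

  set.seed(91)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    res <- bhCorrect(p)
    expect_identical(res$significant, bhOracle(p))
    # adjusted p nondecreasing in raw p
    o <- order(p)
    expect_true(all(diff(res$p.adjusted[o]) >= -1e-12))
  }
})

test_that("BH flags are monotone: lowering one p never unflags another", {
  set.seed(101)
  for (i in 1:10) {
    p <- runif(12)
    base <- bhCorrect(p)$significant
    j <- sample(12, 1)
    p2 <- p; p2[j] <- p[j] / 2
    after <- bhCorrect(p2)$significant
    expect_true(all(after[-j] >= base[-j]))
  }
})

test_that("the full cohort analysis builds the 33-test BH family", {
  tab <- makeCohort(cohortSpec(seed = 111))
  res <- runCohortStats(tab)
  expect_equal(nrow(res$bhFamily), 33)
  expect_equal(nrow(res$twoway), 11)
  expect_equal(nrow(res$gg), 11)
  expect_equal(nrow(res$zone), 11)
  expect_equal(nrow(res$biopsy), 11)
  # Tukey tables exist exactly for the BH-significant ANOVA parameters
  want <- c(paste0(res$twoway$parameter[res$twoway$sig.pirads], ".pirads"),
            paste0(res$gg$parameter[res$gg$sig], ".gg"))
  expect_setequal(names(res$tukey), want)
})

test_that("zone analyses are skipped and logged for a one-zone cohort", {
  tab <- makeCohort(cohortSpec(seed = 121))
  tab <- tab[tab$zone == "PZ", ]
  res <- runCohortStats(tab)
  expect_null(res$zone)
  expect_true(all(c("zone_ttest", "twoway_anova") %in%
                    res$skipped$analysis))
  expect_false(is.null(res$gg))  # PZ-only analyses still run
})
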