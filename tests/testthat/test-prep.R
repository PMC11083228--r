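test_that("arrival detection matches a brute-force threshold scan", {
  # zero through frame 20, then a steep ramp: arrival at frame 21 (the
  # first frame after 20 zero frames)
  curve <- c(rep(0, 20), seq(1, 50, length.out = 30))
  expect_equal(detectArrival(curve), 21L)

  expect_error(detectArrival(rep(5, 40)), class = "dceDetectionError")
  expect_error(detectArrival(c(1, 2, 3)), class = "dceDetectionError")
})

test_that("arrival detection recovers a known noisy bolus within one frame", {
  aif <- stdAif()  # truth arrival at frame 16
  hits <- vapply(1:25, function(s) {
    set.seed(s)
    # arterial signal at SNR 50 relative to baseline
    sig <- 100 * (1 + aifValues(aif)) + rnorm(stdGrid$n, 0, 100 / 50)
    detectArrival(sig)
  }, integer(1))
  expect_true(all(abs(hits - arrivalFrame(aif)) <= 1))
})

test_that("baseline excludes the first two frames and pre-arrival only", {
  arr <- array(rep(c(80, 85, 90:97, rep(200, 5)), each = 8),
               dim = c(2, 2, 2, 15))
  ser <- DynamicSeries(arr, dtSeconds = 1.695)
  # arrival at (1-based) frame 11: baseline frames 3..10 hold 90..97
  s0 <- computeBaseline(ser, 11L)
  expect_equal(unique(as.vector(s0)), mean(90:97))  # 93.5 by hand
  expect_equal(unique(as.vector(s0)), 93.5)

  s0c <- computeBaseline(DynamicSeries(array(100, dim = c(1, 1, 1, 12)),
                                       dtSeconds = 1), 10L)
  expect_equal(as.vector(s0c), 100)
  expect_error(computeBaseline(ser, 3L), class = "dceWindowError")
})

test_that("concentration conversion is exact, linear in R and scale-free", {
  n <- 10
  arr <- array(100, dim = c(1, 1, 1, n))
  arr[1, 1, 1, 6] <- 150
  ser <- DynamicSeries(arr, dtSeconds = 1)
  s0 <- computeBaseline(ser, 5L)
  conc <- toConcentration(ser, s0, R = 1, arrivalFrame = 5L)
  expect_equal(voxelData(conc)[1, 1, 1, 6], 0.5)
  expect_equal(voxelData(conc)[1, 1, 1, 1], 0)
  conc2 <- toConcentration(ser, s0, R = 2, arrivalFrame = 5L)
  expect_equal(voxelData(conc2)[1, 1, 1, 6], 1.0)

  # multiplying S (hence S0) by any c > 0 leaves C unchanged
  serScaled <- DynamicSeries(arr * 7.3, dtSeconds = 1)
  concS <- toConcentration(serScaled, computeBaseline(serScaled, 5L),
                           R = 1, arrivalFrame = 5L)
  expect_equal(voxelData(concS), voxelData(conc), tolerance = 1e-12)

  # nonpositive baseline flags the voxel instead of failing
  bad <- toConcentration(ser, s0 * 0, R = 1, arrivalFrame = 5L)
  expect_false(any(validMask(bad)))
})

test_that("AIF extraction is the unscaled voxel mean over the artery", {
  n <- 20
  f <- c(rep(0, 9), seq(1, 4, length.out = 11)) + 100
  g <- c(rep(0, 9), seq(2, 6, length.out = 11)) + 100
  arr <- array(100, dim = c(2, 1, 1, n))
  arr[1, 1, 1, ] <- f
  arr[2, 1, 1, ] <- g
  ser <- DynamicSeries(arr, dtSeconds = 1)
  s0 <- computeBaseline(ser, 9L)
  conc <- toConcentration(ser, s0, arrivalFrame = 9L)

  one <- RoiMask(array(c(1, 0), dim = c(2, 1, 1)), "artery")
  both <- RoiMask(array(c(1, 1), dim = c(2, 1, 1)), "artery")
  aifOne <- extractAif(conc, one)
  aifBoth <- extractAif(conc, both)
  expect_equal(aifValues(aifOne), voxelData(conc)[1, 1, 1, ])
  expect_equal(aifValues(aifBoth),
               (voxelData(conc)[1, 1, 1, ] + voxelData(conc)[2, 1, 1, ]) / 2)
  expect_equal(aifBoth@sourceVoxelCount, 2L)
})

test_that("a noisy multi-voxel artery recovers the true AIF within 1% RMS", {
  aif <- stdAif()
  nv <- 20
  set.seed(99)
  arr <- array(0, dim = c(nv, 1, 1, stdGrid$n))
  peakSig <- 100 * (1 + max(aifValues(aif)))
  for (v in seq_len(nv)) {
    arr[v, 1, 1, ] <- 100 * (1 + aifValues(aif)) +
      rnorm(stdGrid$n, 0, 0.01 * peakSig)
  }
  ser <- DynamicSeries(arr, dtSeconds = stdGrid$dt)
  arrival <- detectArrival(colMeans(matrix(arr, nv, stdGrid$n)))
  conc <- toConcentration(ser, computeBaseline(ser, arrival),
                          arrivalFrame = arrival)
  rec <- extractAif(conc, RoiMask(array(1, dim = c(nv, 1, 1)), "artery"))
  rms <- sqrt(mean((aifValues(rec) - aifValues(aif))^2))
  expect_lt(rms / max(aifValues(aif)), 0.01)
})

test_that("the analysis window has 71 frames at the study grid", {
  curve <- seq_len(stdGrid$n)
  w <- cutWindow(curve, arrivalFrame = 16L, durationS = 120,
                 dtSeconds = 1.695)
  expect_length(w$values, 71L)           # floor(120/1.695) = 70 + arrival
  expect_equal(w$timeS[1], 0)
  expect_equal(w$frames[1], 16L)
  expect_false(w$truncated)

  single <- cutWindow(curve, 16L, 0, 1.695)
  expect_length(single$values, 1L)

  late <- cutWindow(curve, 140L, 120, 1.695)
  expect_true(late$truncated)
  expect_length(late$values, stdGrid$n - 140L + 1L)
})

test_that("noiseless tissue concentration is zero before arrival", {
  aif <- stdAif()
  sig <- simulateVoxel("2cu", c(vp = 0.2, ps = 0.4, fp = 0.4), aif,
                       s0 = 100, noiseSd = 0)
  ser <- curveSeries(sig)
  arrival <- arrivalFrame(aif)
  conc <- toConcentration(ser, computeBaseline(ser, arrival),
                          arrivalFrame = arrival)
  pre <- voxelData(conc)[1, 1, 1, seq_len(arrival - 1L)]
  expect_equal(max(abs(pre)), 0, tolerance = 1e-12)
})
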