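test_that("the biexponential starts map to the stated physiology", {
  p <- biexpToPhysio(c(alphaPlus = 0.2, alphaMinus = 0.2, betaMinus = 4))
  expect_equal(p, c(vp = 0.2, ps = 0.4, fp = 0.4))
  b <- physioToBiexp(c(vp = 0.2, ps = 0.4, fp = 0.4))
  expect_equal(b, c(alphaPlus = 0.2, alphaMinus = 0.2, betaMinus = 4))
})

test_that("mapping handles one-compartment and degenerate limits", {
  # alphaPlus = 0 collapses to a plug-flow plasma compartment: E = 0
  expect_error(biexpToPhysio(c(alphaPlus = 0, alphaMinus = 0,
                               betaMinus = 4)),
               class = "dceDegenerateError")
  expect_error(biexpToPhysio(c(alphaPlus = 0.2, alphaMinus = 0,
                               betaMinus = 4)),
               class = "dceInfinitePSError")
  p <- biexpToPhysio(c(alphaPlus = 0, alphaMinus = 0.4, betaMinus = 4))
  expect_equal(p, c(vp = 0.1, ps = 0, fp = 0.4))
  # PS = 0 is outside its credible range (0, 10]
  expect_false(ultraDCE:::.inRange(p[["ps"]], "ps"))
  b <- physioToBiexp(c(vp = 0.1, ps = 0, fp = 0.4))
  expect_equal(b, c(alphaPlus = 0, alphaMinus = 0.4, betaMinus = 4))
})

test_that("biexp <-> physio round-trips on random valid parameters", {
  set.seed(5)
  for (i in 1:50) {
    p <- c(vp = runif(1, 0.01, 5), ps = runif(1, 0.01, 5),
           fp = runif(1, 0.05, 5))
    expect_equal(biexpToPhysio(physioToBiexp(p)), p, tolerance = 1e-10)
  }
})

test_that("the mapping is validated by matching forward curves", {
  # (0.1, 0.3, 2): claimed physiological equivalent checked by comparing
  # the biexp forward curve with the independently built residue-function
  # curve on a dense grid
  b <- c(alphaPlus = 0.1, alphaMinus = 0.3, betaMinus = 2)
  p <- biexpToPhysio(b)
  expect_equal(unname(p), c(0.26667, 0.13333, 0.4), tolerance = 1e-4)
  aif <- stdAif()
  tm <- stdTimesMin()
  # same discretization on both sides isolates the parameter mapping
  cb <- forwardTwoCU(b, aifValues(aif), tm, method = "trapezoid")
  cp <- physioResidueForward(p, aifValues(aif), tm)
  expect_lt(max(abs(cb - cp)), 1e-8 * max(abs(cb)))
})

test_that("derived parameters follow their defining identities", {
  d <- deriveSecondary(c(vp = 0.2, ps = 0.4, fp = 0.4))
  expect_equal(d, c(mttp = 0.25, tc = 0.5, e = 0.5, ktrans = 0.2))
  d0 <- deriveSecondary(c(vp = 0.1, ps = 0, fp = 0.4))
  expect_equal(d0[["e"]], 0)
  expect_equal(d0[["ktrans"]], 0)
  expect_equal(d0[["mttp"]], d0[["tc"]])
  expect_error(deriveSecondary(c(vp = 0.1, ps = 0.4, fp = 0)),
               class = "dceDomainError")

  set.seed(6)
  for (i in 1:25) {
    p <- c(vp = runif(1, 0.01, 3), ps = runif(1, 0.01, 3),
           fp = runif(1, 0.05, 3))
    b <- physioToBiexp(p)
    d <- deriveSecondary(p)
    expect_equal(d[["ktrans"]], b[["alphaPlus"]], tolerance = 1e-12)
    expect_equal(d[["mttp"]], 1 / b[["betaMinus"]], tolerance = 1e-12)
    expect_true(d[["e"]] >= 0 && d[["e"]] <= 1)
    expect_lte(d[["mttp"]], d[["tc"]])
    expect_lte(d[["ktrans"]], min(p[["ps"]], p[["fp"]]) + 1e-12)
  }
})

test_that("convolving a unit-area impulse reproduces the kernel", {
  tm <- stdTimesMin()[1:60]
  b <- c(alphaPlus = 0.2, alphaMinus = 0.2, betaMinus = 4)
  imp <- numeric(60); imp[1] <- 2 / (1.695 / 60)
  out <- forwardTwoCU(b, imp, tm, method = "trapezoid")
  kern <- b[["alphaPlus"]] + b[["alphaMinus"]] * exp(-b[["betaMinus"]] * tm)
  expect_equal(out[2:60], kern[2:60], tolerance = 1e-10)
})

test_that("a boxcar input with alphaMinus = 0 gives the Patlak ramp", {
  dtMin <- 1.695 / 60
  tm <- (0:70) * dtMin
  Tbox <- 30 / 60  # 30 s plateau, minutes
  x <- as.numeric(tm <= Tbox)
  b <- c(alphaPlus = 0.2, alphaMinus = 0, betaMinus = 1)
  out <- forwardTwoCU(b, x, tm)
  exact <- 0.2 * pmin(tm, Tbox)
  # trapezoid error at the box edge is O(dt); compare away from it
  expect_equal(out, exact, tolerance = 2 * 0.2 * dtMin)
})

test_that("trapezoid convolution matches oversampled quadrature and the
           recursive scheme", {
  aif <- stdAif()
  tm <- stdTimesMin()
  set.seed(17)
  for (i in 1:5) {
    p <- c(vp = runif(1, 0.05, 2), ps = runif(1, 0.05, 2),
           fp = runif(1, 0.1, 2))
    b <- physioToBiexp(p)
    b[["betaMinus"]] <- min(b[["betaMinus"]], 10)
    trap <- forwardTwoCU(b, aifValues(aif), tm, method = "trapezoid")
    over <- oversampledConv(b, aifValues(aif), tm, factor = 100)
    rec <- forwardTwoCU(b, aifValues(aif), tm)
    scale <- max(abs(over))
    expect_lt(max(abs(rec - over)) / scale, 1e-3)
    expect_lt(max(abs(trap - over)) / scale, 4e-3)
  }
  expect_error(forwardTwoCU(c(alphaPlus = 1, alphaMinus = 1, betaMinus = 1),
                            c(0, 1, 0), c(0, 0.1, 0.5)),
               class = "dceGridError")
})

test_that("noiseless voxel fits recover the truth within 1-2%", {
  aif <- stdAif()
  aw <- cutWindow(aifValues(aif), arrivalFrame(aif), 120, stdGrid$dt)
  for (truth in list(c(vp = 0.2, ps = 0.4, fp = 0.4),
                     c(vp = 0.05, ps = 0.1, fp = 1.5))) {
    b <- physioToBiexp(truth)
    curve <- forwardTwoCU(b, aw$values, aw$timeMin)
    fit <- fitTwoCUVoxel(curve, aw$values, aw$timeMin)
    expect_true(fit$converged)
    expect_lte(fit$ssr, fit$ssrStart)
    rec <- biexpToPhysio(fit$biexp)
    expect_equal(unname(rec), unname(truth), tolerance = 0.02)
  }
  flat <- fitTwoCUVoxel(rep(0, 71), aw$values, aw$timeMin)
  expect_false(flat$converged)
})

test_that("volume fitting masks out-of-range voxels and empty phantoms", {
  ph <- makePhantom(phantomSpec(dim = c(8, 8, 1), noiseSd = 0, seed = 2,
    arteryBox = list(x = 1:2, y = 1:2, z = 1),
    regions = list(
      list(name = "lesion", label = "lesion", zone = "PZ", model = "2cu",
           params = c(vp = 0.2, ps = 0.4, fp = 0.4),
           box = list(x = 4:6, y = 4:6, z = 1)))))
  arrival <- detectArrival(colMeans(
    matrix(voxelData(ph$series), 64, stdGrid$n)[which(voxelData(ph$masks$artery)), ,
                                                drop = FALSE]))
  conc <- toConcentration(ph$series, computeBaseline(ph$series, arrival),
                          arrivalFrame = arrival)
  aif <- extractAif(conc, ph$masks$artery)
  maps <- fitTwoCUVolume(conc, aif, mask = ph$masks$lesion)
  lesionSel <- voxelData(ph$masks$lesion)
  expect_true(all(validMask(maps$fp)[lesionSel]))
  expect_equal(median(voxelData(maps$fp)[lesionSel]), 0.4, tolerance = 0.02)
  expect_equal(median(voxelData(maps$vp)[lesionSel]), 0.2, tolerance = 0.02)
  # voxels never fitted stay invalid with NaN values
  expect_false(any(validMask(maps$fp)[!lesionSel]))
  expect_true(all(is.nan(voxelData(maps$fp)[!lesionSel])))
})
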