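# Independent numerical oracles used across the suite. These deliberately
# avoid the package's convolution/fitting code paths.

# Dense-grid quadrature of the biexponential-kernel convolution: linear
# interpolation of the input on an `factor`-times finer grid, exact kernel
# evaluation, trapezoidal integration, subsampled back to the grid.
oversampledConv <- function(b, aifValues, timesMin, factor = 100) {
  n <- length(timesMin)
  dt <- timesMin[2] - timesMin[1]
  fine <- seq(timesMin[1], timesMin[n], by = dt / factor)
  aFine <- approx(timesMin, aifValues, xout = fine)$y
  dtF <- dt / factor
  out <- numeric(n)
  for (i in 2:n) {
    tEnd <- timesMin[i]
    sel <- fine <= tEnd + 1e-12
    tau <- tEnd - fine[sel]
    kern <- b[["alphaPlus"]] + b[["alphaMinus"]] * exp(-b[["betaMinus"]] * tau)
    y <- aFine[sel] * kern
    out[i] <- dtF * (sum(y) - 0.5 * y[1] - 0.5 * y[length(y)])
  }
  out
}

# Forward curve built from the *physiological* residue-function form
# Fp * [E + (1 - E) exp(-t / MTTp)] (x) AIF — an independent construction
# of the same model used to check the biexp <-> physio mapping.
physioResidueForward <- function(p, aifValues, timesMin) {
  der <- c(mttp = p[["vp"]] / (p[["ps"]] + p[["fp"]]),
           e = p[["ps"]] / (p[["ps"]] + p[["fp"]]))
  kern <- p[["fp"]] * (der[["e"]] +
                         (1 - der[["e"]]) * exp(-timesMin / der[["mttp"]]))
  n <- length(timesMin)
  dt <- timesMin[2] - timesMin[1]
  out <- numeric(n)
  for (i in 2:n) {
    y <- aifValues[1:i] * kern[i:1]
    out[i] <- dt * (sum(y) - 0.5 * y[1] - 0.5 * y[i])
  }
  out
}

# Brute-force Benjamini-Hochberg step-up: largest i with p_(i) <= i q / m
# flags all hypotheses with p <= that cutoff.
bhOracle <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) * q / m)
  flags <- rep(FALSE, m)
  if (length(ok)) flags[p <= p[o[max(ok)]]] <- TRUE
  flags
}

# Shared acquisition grid matching the study protocol.
stdGrid <- list(dt = 1.695, n = 150L)
stdTimesMin <- function() (seq_len(stdGrid$n) - 1) * stdGrid$dt / 60

stdAif <- function() makeAif(aifSpec(), stdGrid$n, stdGrid$dt)

# A tiny single-voxel DynamicSeries wrapping one signal curve.
curveSeries <- function(curve, dt = stdGrid$dt) {
  DynamicSeries(array(curve, dim = c(1, 1, 1, length(curve))), dtSeconds = dt)
}
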