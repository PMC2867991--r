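test_that("logistic map matches direct iteration and fixed points", {
  # independent high-precision iteration, including burn-in
  r <- 4; x <- 0.2
  for (k in 1:1003) x <- r * x * (1 - x)
  got <- logisticSeries(4, 0.2, 5)
  expect_identical(got[3], x)
  expect_equal(logisticSeries(2, 0.3, 10), rep(0.5, 10), tolerance = 1e-12)
  expect_identical(logisticSeries(4, 0, 5), rep(0, 5))
  expect_error(logisticSeries(5, 0.2, 10), "r")
})

test_that("Henon orbits stay bounded and degenerate limits hold", {
  h <- henonSeries(1.4, 0.3, 20000)
  expect_true(all(abs(h$x) < 1.5))
  expect_true(all(abs(h$y) < 0.45))
  # b = 0 reduces to the 1-D quadratic map
  h0 <- henonSeries(1.2, 0, 50)
  expect_true(all(h0$y == 0))
  x <- 0; for (k in 1:1001) x <- 1 - 1.2 * x^2
  expect_identical(h0$x[1], x)
  expect_error(henonSeries(3, 0.9, 100), "diverged")
})

test_that("Lorenz integration decays for rho < 1 and is bounded on the attractor", {
  dec <- lorenzSeries(rho = 0.5, dt = 0.01, n = 3000)
  end <- sqrt(dec$x[3000]^2 + dec$y[3000]^2 + dec$z[3000]^2)
  expect_lt(end, 1e-3)
  # energy-like norm decays monotonically over coarse windows
  nrm <- sqrt(dec$x^2 + dec$y^2 + dec$z^2)
  coarse <- nrm[seq(1, 3000, by = 300)]
  expect_true(all(diff(coarse) < 0))
  att <- lorenzSeries(n = 5000)
  expect_lt(max(abs(att$z)), 60)
  expect_true(all(is.finite(att$x)))
  expect_error(lorenzSeries(dt = 0.1, n = 10), "dt")
})

test_that("stochastic generators are seeded, pure and labelled correctly", {
  expect_identical(whiteSeries(1, 100, seed = 5), whiteSeries(1, 100, seed = 5))
  expect_identical(arSeries(numeric(0), 2, 50, seed = 3),
                   whiteSeries(2, 50, seed = 3))
  w <- whiteSeries(1, 10000, seed = 6)
  expect_lt(abs(mean(w)), 4 / sqrt(10000))
  expect_error(arSeries(c(1.2), 1, 100, seed = 1), "non-stationary")
  # tone location via direct FFT
  s <- sineMix(10, 2, 250, 2500)
  pw <- Mod(fft(s))[2:1250]
  expect_equal(which.max(pw), 100L)   # 10 Hz at df = 0.1 Hz
})

test_that("synthetic recordings have the contracted shape and structure", {
  spec <- defaultTaskSpecs()$relax
  rec <- syntheticRecording(spec, seed = 3)
  expect_s4_class(rec, "Recording")
  expect_identical(leadLabels(rec),
                   c("C3", "C4", "P3", "P4", "O1", "O2", "EOG"))
  expect_equal(nSamples(rec), 2500L)
  expect_true(validObject(rec))
  expect_identical(sampleMatrix(syntheticRecording(spec, seed = 3)),
                   sampleMatrix(rec))
  # alpha-dominant spec: alpha band beats beta band on C3
  wins <- 0L
  aspec <- taskClassSpec("alphaheavy", alphaRelPower = 6, betaRelPower = 0.2)
  for (i in 1:10) {
    r <- syntheticRecording(aspec, seed = i)
    sp <- arSpectrum(getLead(r, "C3"), fs = 250)
    if (bandEnergy(sp, 8, 13) > bandEnergy(sp, 14, 30)) wins <- wins + 1L
  }
  expect_gte(wins, 10L)
})

test_that("pure-chaos recordings reduce to a scaled Lorenz trace with lambda1 > 0", {
  spec <- taskClassSpec("pure", chaosMix = 1, amplitudeScale = 2)
  rec <- syntheticRecording(spec, seed = 4, eogLeakage = 0)
  x <- getLead(rec, "C3")
  lz <- lorenzSeries(dt = 1 / 250, n = 2500 + 50 * 5)$x
  lz <- (lz - mean(lz)) / sd(lz)
  expect_equal(x, 2 * lz[1:2500], tolerance = 1e-12)
  lam <- lyapunovFromRecording(rec, analysisConfig(), leads = "C3")
  expect_gt(as.numeric(lam), 0)
})

test_that("datasets are reproducible, balanced and correctly ordered by complexity", {
  ds <- syntheticDataset(nPerClass = 3, seed = 11)
  expect_length(ds$recordings, 15L)
  expect_true(all(table(ds$labels) == 3L))
  ds2 <- syntheticDataset(nPerClass = 3, seed = 11)
  expect_identical(lapply(ds$recordings, sampleMatrix),
                   lapply(ds2$recordings, sampleMatrix))
  expect_identical(ds$labels, ds2$labels)
  dup <- list(taskClassSpec("a"), taskClassSpec("a"))
  expect_error(syntheticDataset(dup, nPerClass = 2), "duplicate")
  # complexity ordering at r = 0.5 SD: rotate above math
  apMean <- function(ds, cl)
    mean(sapply(which(ds$labels == cl), function(i)
      apenScaled(getLead(ds$recordings[[i]], "C3"), 2, 0.5)))
  wins <- 0L
  for (s in 1:5) {
    d <- syntheticDataset(nPerClass = 3, seed = 100 + s)
    if (apMean(d, "rotate") > apMean(d, "math")) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
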