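test_that("Burg recovers known AR coefficients", {
  x1 <- arSeries(0.9, sigma = 1, n = 4000, seed = 3)
  m1 <- burgFit(x1, 1)
  expect_equal(m1$coefficients, 0.9, tolerance = 0.05 / 0.9)
  expect_equal(m1$sigma2, 1, tolerance = 0.1)
  x2 <- arSeries(c(1.5, -0.8), sigma = 1, n = 4000, seed = 4)
  m2 <- burgFit(x2, 2)
  expect_lt(max(abs(m2$coefficients - c(1.5, -0.8))), 0.05)
  # degenerate order: sigma2 is the mean square
  m0 <- burgFit(x1, 0)
  expect_identical(m0$order, 0L)
  expect_length(m0$coefficients, 0)
  expect_identical(m0$sigma2, mean(x1^2))
  expect_error(burgFit(x1, 2000), "too large")
  expect_error(burgFit(rep(1, 100), 2), "degenerate")
})

test_that("Burg reflection coefficients are bounded by 1 on random inputs", {
  set.seed(24)
  for (rep in 1:8) {
    x <- cumsum(rnorm(300)) + rnorm(300)
    fit <- burgFit(x, 12)
    expect_true(all(abs(fit$reflection) < 1))
    expect_true(all(diff(fit$sigma2_by_order) <= 1e-12))
  }
})

test_that("AIC selects parsimonious correct orders", {
  whiteOrders <- sapply(1:20, function(i)
    as.integer(aicOrder(whiteSeries(1, 2000, seed = i), 10)))
  expect_gte(mean(whiteOrders <= 2), 0.9)
  # plain AIC overfits with probability ~0.27 here, so the defensible
  # properties are: never underfit, mode at the true order
  ar2Orders <- sapply(1:20, function(i)
    as.integer(aicOrder(arSeries(c(1.5, -0.8), 1, 4000, seed = 100 + i), 10)))
  expect_true(all(ar2Orders >= 2))
  expect_gte(mean(ar2Orders == 2), 0.5)
  expect_identical(as.integer(aicOrder(whiteSeries(1, 500, seed = 1), 0)), 0L)
})

test_that("AR spectra match closed forms", {
  # white noise: flat two-sided density 1/fs
  flat <- arPSD(arModel(numeric(0), sigma2 = 1), fs = 250, nfft = 1024)
  expect_true(all(abs(flat$psd - 1 / 250) < 1e-15))
  expect_equal(flat$frequencies[1], 0)
  expect_equal(max(flat$frequencies), 125)
  # AR(1) a = 0.9: P(0)/P(Nyquist) = ((1+0.9)/(1-0.9))^2 = 361
  sp <- arPSD(arModel(0.9, 1), fs = 250, nfft = 1024)
  expect_equal(sp$psd[1] / sp$psd[length(sp$psd)], 361, tolerance = 1e-10)
  # spectral peak location for a tonal signal
  x <- sineMix(10, 1, 250, 2000) + whiteSeries(0.05, 2000, seed = 7)
  spx <- arPSD(burgFit(x, 8), fs = 250, nfft = 1024)
  fmax <- spx$frequencies[which.max(spx$psd)]
  expect_lt(abs(fmax - 10), 250 / 1024 + 1e-9)
  expect_error(arPSD(arModel(rep(0.1, 10), 1), fs = 250, nfft = 16), "nfft")
})

test_that("band energies integrate the PSD consistently", {
  flat <- arPSD(arModel(numeric(0), sigma2 = 1), fs = 250, nfft = 1024)
  c0 <- 1 / 250
  expect_equal(bandEnergy(flat, 8, 13), 5 * c0, tolerance = 1e-12)
  # disjoint bands tile the total integral
  sp <- arPSD(burgFit(arSeries(0.9, 1, 1000, seed = 2), 4), 250, 1024)
  total <- bandEnergy(sp, 0, 125)
  parts <- bandEnergy(sp, 0, 8) + bandEnergy(sp, 8, 13) +
    bandEnergy(sp, 13, 14) + bandEnergy(sp, 14, 30) + bandEnergy(sp, 30, 125)
  expect_equal(parts, total, tolerance = 1e-9)
  # 10 Hz tone: alpha dominates beta
  x <- sineMix(10, 1, 250, 2000) + whiteSeries(0.05, 2000, seed = 8)
  spx <- arSpectrum(x, fs = 250)
  expect_gt(bandEnergy(spx, 8, 13) / bandEnergy(spx, 14, 30), 10)
  expect_error(bandEnergy(spx, 100, 150), "Nyquist")
})

test_that("the two-sided AR spectrum integral recovers the variance", {
  for (sd_ in 1:4) {
    x <- arSeries(c(1.5, -0.8), 1, 3000, seed = 40 + sd_)
    sp <- arPSD(burgFit(x, 2), fs = 1, nfft = 4096)
    tot <- 2 * bandEnergy(sp, 0, 0.5)
    expect_equal(tot, var(x), tolerance = 0.1 * var(x))
  }
})

test_that("AR spectra of 1/f-like noise decay monotonically in log-log", {
  # integrated-noise proxy for pink noise: strong low-frequency dominance
  x <- arSeries(0.95, 1, 4000, seed = 9)
  sp <- arSpectrum(x, fs = 250, nfft = 1024)
  sel <- sp$frequencies > 1 & sp$frequencies < 100
  fit <- lm(log(sp$psd[sel]) ~ log(sp$frequencies[sel]))
  expect_lt(coef(fit)[2], 0)
})
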