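test_that("correlation integral matches direct pair counts", {
  pts <- rbind(c(0, 0), c(3, 4), c(6, 8))   # pairwise distances 5, 5, 10
  tr <- new("EmbeddedTrajectory", points = pts, m = 2L, tau = 0L,
            sourceN = 3L)
  expect_equal(correlationIntegral(tr, r = 6, w = 0), 2 / 3)
  expect_equal(correlationIntegral(tr, r = 11, w = 0), 1)
  expect_error(correlationIntegral(tr, r = 1, w = 2), "no admissible")
})

test_that("correlation integral equals the brute-force count on random clouds", {
  set.seed(17)
  for (rep in 1:6) {
    M <- sample(50:300, 1)
    d <- sample(2:4, 1)
    w <- sample(0:5, 1)
    pts <- matrix(rnorm(M * d), M, d)
    tr <- new("EmbeddedTrajectory", points = pts, m = as.integer(d),
              tau = 0L, sourceN = as.integer(M))
    r <- runif(1, 0.5, 3)
    expect_identical(correlationIntegral(tr, r, w),
                     corrIntegralBrute(pts, r, w))
  }
})

test_that("correlation curves are monotone, scale-equivariant, and validated", {
  set.seed(18)
  pts <- matrix(rnorm(400), 200, 2)
  tr <- new("EmbeddedTrajectory", points = pts, m = 2L, tau = 0L,
            sourceN = 200L)
  radii <- exp(seq(log(0.05), log(6), length.out = 15))
  cv <- correlationCurve(tr, radii, w = 0)
  expect_true(all(diff(cv$ln_c) >= 0))
  # doubling coordinates shifts ln r by ln 2 at identical ln C
  tr2 <- new("EmbeddedTrajectory", points = 2 * pts, m = 2L, tau = 0L,
             sourceN = 200L)
  cv2 <- correlationCurve(tr2, 2 * radii, w = 0)
  expect_equal(cv2$ln_c, cv$ln_c)
  expect_equal(cv2$ln_r, cv$ln_r + log(2))
  # all-identical points: C = 1 for every radius
  tri <- new("EmbeddedTrajectory", points = matrix(1, 50, 2), m = 2L,
             tau = 0L, sourceN = 50L)
  cvi <- correlationCurve(tri, radii, w = 0)
  expect_true(all(cvi$ln_c == 0))
  expect_error(correlationCurve(tr, radii[1:4], 0), "at least 5")
  expect_error(correlationCurve(tr, seq(1, 2, length.out = 8), 0),
               "1.5 decades")
})

test_that("scaling-region detection finds lines and rejects jitter", {
  ln_r <- seq(log(0.01), log(1), length.out = 20)
  # exact line of slope 2: whole curve, slope 2
  cv <- structure(list(ln_r = ln_r, ln_c = 2 * ln_r - 0.5, theiler_w = 0L,
                       n_points = 100L), class = "CorrelationCurve")
  reg <- suppressWarnings(findScalingRegion(cv, tol = 0.01))
  expect_equal(reg$from, 1L)
  expect_equal(reg$to, 20L)
  expect_equal(reg$slope, 2, tolerance = 1e-12)
  # piecewise: slope 2 for 10 points then flat (saturation)
  lc <- c(2 * ln_r[1:10], rep(2 * ln_r[10], 10))
  cvp <- structure(list(ln_r = ln_r, ln_c = lc, theiler_w = 0L,
                        n_points = 100L), class = "CorrelationCurve")
  regp <- suppressWarnings(findScalingRegion(cvp, tol = 0.01))
  expect_lte(regp$to, 10L)
  expect_equal(regp$slope, 2, tolerance = 1e-12)
  # 5% slope jitter at 1% tolerance: no window of 10 points survives
  # (centred differencing halves the jitter, so short windows can pass by
  # chance; the counterexample asks for a usable-length region)
  set.seed(19)
  slopes <- 2 * (1 + runif(19, -0.05, 0.05))
  lnj <- cumsum(c(0, slopes * diff(ln_r)))
  cvj <- structure(list(ln_r = ln_r, ln_c = lnj, theiler_w = 0L,
                        n_points = 100L), class = "CorrelationCurve")
  err <- tryCatch(findScalingRegion(cvj, tol = 0.01, minLen = 10),
                  noScalingRegionError = function(e) e)
  expect_s3_class(err, "noScalingRegionError")
  expect_true(is.finite(err$best_fluctuation))
})

test_that("analytic dimensions are recovered: line D2 = 1, square D2 = 2", {
  set.seed(20)
  tpar <- sort(runif(2000))
  line <- new("EmbeddedTrajectory",
              points = cbind(tpar, 0.5 * tpar + 0.2), m = 2L, tau = 0L,
              sourceN = 2000L)
  expect_equal(correlationDimension(line, w = 0)$D2, 1, tolerance = 0.05)
  sq <- new("EmbeddedTrajectory",
            points = cbind(runif(2000), runif(2000)), m = 2L, tau = 0L,
            sourceN = 2000L)
  expect_equal(correlationDimension(sq, w = 0)$D2, 2, tolerance = 0.05)
})

test_that("noise dimension grows with embedding dimension, Henon saturates", {
  hx <- henonSeries(1.4, 0.3, 4000)$x
  dh <- sapply(2:4, function(m)
    correlationDimension(delayEmbed(hx, m, 1), w = 10)$D2)
  expect_lt(max(dh) - min(dh), 0.3)
  dn <- sapply(2:4, function(m)
    correlationDimension(delayEmbed(whiteSeries(1, 2000, seed = m), m, 1),
                         w = 0)$D2)
  expect_true(all(diff(dn) > 0.5))
  expect_gt(dn[3] - dh[3], 1.5)
})

test_that("a Theiler window never worsens the noisy-map dimension estimate", {
  # temporally close pairs bias D2 downward; excluding them (w = mean
  # period) must not increase that underestimate (ensemble check)
  set.seed(26)
  x0s <- runif(6, 0.05, 0.45)
  d0 <- dp <- numeric(6)
  for (i in 1:6) {
    x <- logisticSeries(4, x0s[i], 1500) +
      whiteSeries(0.001, 1500, seed = i)
    tr <- delayEmbed(x, 2, 1)
    d0[i] <- correlationDimension(tr, w = 0)$D2
    dp[i] <- correlationDimension(tr, w = meanPeriod(x, 1))$D2
  }
  expect_gte(mean(dp), mean(d0))
})
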