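test_that("nearest neighbours respect the temporal exclusion", {
  # two tight clusters far apart in time: with the exclusion active, each
  # point must pair across clusters
  pts <- cbind(c(0, 0.01, 0.02, 5, 5.01, 5.02), 0)
  tr <- new("EmbeddedTrajectory", points = pts, m = 2L, tau = 0L,
            sourceN = 6L)
  pr <- nearestNeighborPairs(tr, minSep = 2)
  brute <- sapply(1:6, function(j) {
    cand <- setdiff(which(abs(seq_len(6) - j) > 2), j)
    cand[which.min(sqrt(rowSums((pts[cand, , drop = FALSE] -
                                   matrix(pts[j, ], length(cand), 2,
                                          byrow = TRUE))^2)))]
  })
  expect_equal(pr$nn, as.integer(brute))
  expect_true(all(pr$nn[1:3] >= 4))
  # minSep = 0: plain nearest neighbour
  p2 <- cbind(c(0, 0.1, 5), 0)
  t2 <- new("EmbeddedTrajectory", points = p2, m = 2L, tau = 0L,
            sourceN = 3L)
  expect_equal(nearestNeighborPairs(t2, 0)$nn[1], 2L)
  expect_error(nearestNeighborPairs(t2, 3), "no admissible")
})

test_that("divergence curves reproduce constructed separations exactly", {
  # two parallel trajectories at constant distance c
  n <- 40
  base <- cbind(seq_len(n), 0)
  pts <- rbind(base, cbind(seq_len(n), 3))
  tr <- new("EmbeddedTrajectory", points = pts, m = 2L, tau = 0L,
            sourceN = as.integer(2 * n))
  pairing <- structure(list(nn = c((n + 1):(2 * n), 1:n),
                            dist = rep(3, 2 * n), minSep = 0L),
                       class = "NNPairs")
  cv <- divergenceCurve(tr, pairing, maxSteps = 10)
  expect_equal(cv$y, rep(log(3), 11))
  expect_true(all(diff(cv$n_pairs) <= 0))
  # exponential construction: one tracked pair with d(i) = d0 * exp(0.5 i)
  i <- 0:15
  pts2 <- cbind(c(0.001 * exp(0.5 * i), rep(0, 16)), rep(0, 32))
  tr2 <- new("EmbeddedTrajectory", points = pts2, m = 2L, tau = 0L,
             sourceN = 32L)
  pairing2 <- structure(list(nn = c(17L, rep(NA_integer_, 31)),
                             dist = rep(NA_real_, 32), minSep = 0L),
                        class = "NNPairs")
  cv2 <- divergenceCurve(tr2, pairing2, maxSteps = 15)
  expect_equal(cv2$y, log(0.001) + 0.5 * (0:15), tolerance = 1e-12)
  expect_equal(maxLyapunov(cv2, 0, 15), 0.5, tolerance = 1e-12)
})

test_that("divergence curve equals brute-force recomputation on an embedding", {
  x <- logisticSeries(4, 0.31, 400)
  tr <- delayEmbed(x, 2, 1)
  pr <- nearestNeighborPairs(tr, minSep = 10)
  cv <- divergenceCurve(tr, pr, maxSteps = 12)
  expect_equal(cv$y, divergenceBrute(trajectoryPoints(tr), pr$nn, 12),
               tolerance = 1e-12)
})

test_that("lambda1 recovers ln 2 for the logistic map and ~0 for a sinusoid", {
  x <- logisticSeries(4, 0.2, 5000)
  lam <- lyapunovExponent(x, m = 2, tau = 1, minSep = 10,
                          fitLo = 1, fitHi = 8)
  expect_equal(as.numeric(lam), log(2), tolerance = 0.1 / log(2))
  # incommensurate tone frequency so neighbours sit at small nonzero
  # distances (an exact 25-sample period makes every neighbour an exact
  # duplicate, which the zero-distance policy drops)
  s <- sineMix(9.7, 1, 250, 3000)
  trs <- delayEmbed(s, 4, 3)
  prs <- nearestNeighborPairs(trs, minSep = 26)
  cvs <- divergenceCurve(trs, prs, maxSteps = 12)
  expect_lt(abs(maxLyapunov(cvs, 0, 8)), 0.02)
})

test_that("lambda1 for the Henon map matches the Benettin oracle within 20%", {
  h <- henonSeries(1.4, 0.3, 10000)
  lam <- lyapunovExponent(h$x, m = 2, tau = 1, minSep = 10,
                          fitLo = 1, fitHi = 8)
  oracle <- benettinHenon(n = 50000L)
  expect_lt(abs(as.numeric(lam) - oracle) / oracle, 0.2)
})

test_that("lambda1 is invariant under amplitude scaling", {
  x <- logisticSeries(4, 0.41, 2000)
  l1 <- lyapunovExponent(x, 2, 1, minSep = 10, fitLo = 1, fitHi = 8)
  l2 <- lyapunovExponent(100 * x, 2, 1, minSep = 10, fitLo = 1, fitHi = 8)
  expect_equal(as.numeric(l1), as.numeric(l2), tolerance = 1e-10)
})

test_that("recording-level lambda1 recovers the Lorenz exponent via splicing", {
  lz <- lorenzSeries(dt = 0.01, n = 5000)$x
  rec <- Recording(rbind(rbind(lz[1:2500], lz[2501:5000]),
                         matrix(rep(lz[1:2500], 5), nrow = 5, byrow = TRUE)),
                   fs = 100,
                   leadLabels = c("C3", "C4", "P3", "P4", "O1", "O2", "EOG"))
  cfg <- analysisConfig()
  lam <- lyapunovFromRecording(rec, cfg, leads = "C3")
  oracle <- benettinLorenz(n = 100000L)
  expect_lt(abs(as.numeric(lam) - oracle) / oracle, 0.25)
  # splicing two segments of the same flow agrees with the single-lead run
  lam2 <- lyapunovFromRecording(rec, cfg, leads = c("C3", "C4"))
  expect_gt(as.numeric(lam2), 0)
  expect_equal(as.numeric(lam2), as.numeric(lam), tolerance = 0.3)
})

test_that("stochastic recordings fail the stable-window rule", {
  set.seed(23)
  rec <- Recording(matrix(rnorm(7 * 1500), nrow = 7), fs = 250,
                   leadLabels = c("C3", "C4", "P3", "P4", "O1", "O2", "EOG"))
  expect_error(lyapunovFromRecording(rec, analysisConfig(), leads = "C3"),
               class = "noFitWindowError")
})
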