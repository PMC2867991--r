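# Independent brute-force oracles used to pin expected values. These are
# deliberately naive re-derivations (direct loops/enumeration), kept separate
# from the package's computational paths.

# Naive ApEn: build all templates, enumerate all pairs.
apenBrute <- function(x, m, r, selfMatches = TRUE) {
  n <- length(x)
  phi <- function(mm) {
    nv <- n - mm + 1L
    V <- sapply(seq_len(mm), function(k) x[k:(k + nv - 1L)])
    if (nv == 1L) V <- matrix(V, nrow = 1L)
    ci <- sapply(seq_len(nv), function(i) {
      d <- apply(abs(sweep(V, 2L, V[i, ], "-")), 1L, max)
      if (selfMatches) sum(d <= r) / (n - mm + 1L)
      else (sum(d <= r) - 1L) / (n - mm)
    })
    mean(log(ci))
  }
  phi(m) - phi(m + 1L)
}

# Naive correlation integral: enumerate all pairs.
corrIntegralBrute <- function(pts, r, w = 0L) {
  M <- nrow(pts)
  cnt <- 0L; adm <- 0L
  for (i in seq_len(M - 1L)) {
    for (j in (i + 1L):M) {
      if (j - i <= w) next
      adm <- adm + 1L
      if (sqrt(sum((pts[i, ] - pts[j, ])^2)) < r) cnt <- cnt + 1L
    }
  }
  cnt / adm
}

# Naive divergence curve from an explicit pairing.
divergenceBrute <- function(pts, nn, maxSteps) {
  M <- nrow(pts)
  sapply(0:maxSteps, function(i) {
    vals <- c()
    for (j in seq_len(M)) {
      q <- nn[j]
      if (is.na(q) || j + i > M || q + i > M) next
      d <- sqrt(sum((pts[j + i, ] - pts[q + i, ])^2))
      if (d > 0) vals <- c(vals, log(d))
    }
    if (length(vals)) mean(vals) else NA_real_
  })
}

# Benettin (tangent-map) oracle for the Henon map's largest Lyapunov
# exponent: multiply Jacobians along the orbit with renormalisation.
benettinHenon <- function(a = 1.4, b = 0.3, n = 100000L) {
  x <- 0; y <- 0
  for (k in 1:1000) { xn <- 1 - a * x^2 + y; y <- b * x; x <- xn }
  v <- c(1, 0); acc <- 0
  for (k in seq_len(n)) {
    v <- c(-2 * a * x * v[1] + v[2], b * v[1])
    nv <- sqrt(sum(v^2)); acc <- acc + log(nv); v <- v / nv
    xn <- 1 - a * x^2 + y; y <- b * x; x <- xn
  }
  acc / n
}

# Benettin oracle for the Lorenz flow: RK4 on the variational system.
benettinLorenz <- function(sigma = 10, rho = 28, beta = 8 / 3, dt = 0.005,
                           n = 200000L) {
  deriv <- function(s, v) {
    list(c(sigma * (s[2] - s[1]), s[1] * (rho - s[3]) - s[2],
           s[1] * s[2] - beta * s[3]),
         c(-sigma * v[1] + sigma * v[2],
           (rho - s[3]) * v[1] - v[2] - s[1] * v[3],
           s[2] * v[1] + s[1] * v[2] - beta * v[3]))
  }
  s <- c(1, 1, 1); v <- c(1, 0, 0); acc <- 0
  for (k in 1:2000) s <- s + dt * deriv(s, v)[[1]]
  for (k in seq_len(n)) {
    a1 <- deriv(s, v)
    a2 <- deriv(s + dt / 2 * a1[[1]], v + dt / 2 * a1[[2]])
    a3 <- deriv(s + dt / 2 * a2[[1]], v + dt / 2 * a2[[2]])
    a4 <- deriv(s + dt * a3[[1]], v + dt * a3[[2]])
    s <- s + dt / 6 * (a1[[1]] + 2 * a2[[1]] + 2 * a3[[1]] + a4[[1]])
    v <- v + dt / 6 * (a1[[2]] + 2 * a2[[2]] + 2 * a3[[2]] + a4[[2]])
    if (k %% 20 == 0) {
      nv <- sqrt(sum(v^2)); acc <- acc + log(nv); v <- v / nv
    }
  }
  acc / (n * dt)
}

# Pinned once from an independent large-N brute-force Grassberger-Procaccia
# pair count (N = 50000 delay-embedded Henon points, m = 2, tau = 1,
# Theiler window 10; least-squares slope over the scaling plateau).
HENON_D2_ORACLE <- 1.1994

# Small convenience: a Recording with given lead series.
makeRecording <- function(..., fs = 250) {
  leads <- list(...)
  Recording(do.call(rbind, leads), fs = fs, leadLabels = names(leads))
}
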