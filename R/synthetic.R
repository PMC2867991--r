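#' Logistic-map series
#'
#' Iterates `x_{k+1} = r x_k (1 - x_k)` from `x0`, discarding a burn-in.
#' At `r = 4` the map is fully chaotic with largest Lyapunov exponent
#' `ln 2` per iteration — the standard analytic validation fixture.
#'
#' @param r map parameter, `0 < r <= 4`.
#' @param x0 initial value in `[0, 1)`.
#' @param n output length.
#' @param burn burn-in iterations discarded (default 1000).
#' @return Numeric series of length `n`.
#' @export
logisticSeries <- function(r, x0, n, burn = 1000L) {
  stopifnot(r > 0, r <= 4, x0 >= 0, x0 < 1, n >= 1)
  total <- n + burn
  out <- numeric(total)
  x <- x0
  for (k in seq_len(total)) {
    x <- r * x * (1 - x)
    out[k] <- x
  }
  out[(burn + 1L):total]
}

#' Henon-map series
#'
#' Iterates `x_{k+1} = 1 - a x_k^2 + y_k`, `y_{k+1} = b x_k` from the
#' standard basin start `(0, 0)`, discarding a burn-in. The classical
#' parameters `a = 1.4`, `b = 0.3` give the strange attractor with
#' correlation dimension about 1.2 and `lambda1` about 0.42 per iteration.
#'
#' @param a,b map parameters.
#' @param n output length.
#' @param burn burn-in iterations (default 1000).
#' @return List with numeric series `x` and `y`.
#' @export
henonSeries <- function(a = 1.4, b = 0.3, n, burn = 1000L) {
  stopifnot(n >= 1)
  total <- n + burn
  xs <- numeric(total); ys <- numeric(total)
  x <- 0; y <- 0
  for (k in seq_len(total)) {
    xn <- 1 - a * x^2 + y
    y <- b * x
    x <- xn
    if (!is.finite(x) || abs(x) > 1e10)
      stop(sprintf("Henon orbit diverged at iteration %d (a = %g, b = %g)",
                   k, a, b))
    xs[k] <- x; ys[k] <- y
  }
  keep <- (burn + 1L):total
  list(x = xs[keep], y = ys[keep])
}

#' Lorenz-flow series
#'
#' Integrates the Lorenz system `dx = sigma (y - x)`,
#' `dy = x (rho - z) - y`, `dz = x y - beta z` with a fixed-step 4th-order
#' Runge-Kutta scheme, discarding a burn-in of `burnTime` time units. The
#' classical parameters (10, 28, 8/3) give the chaotic attractor with
#' `lambda1` about 0.9 per time unit; a flow sampled at EEG-like rates is
#' the chaotic ingredient of the synthetic recordings.
#'
#' @param sigma,rho,beta flow parameters.
#' @param dt integration/sampling step (<= 0.02).
#' @param n number of output samples.
#' @param burnTime burn-in in time units (default 10).
#' @param state0 initial state (default `c(1, 1, 1)`).
#' @return List with numeric series `x`, `y`, `z`.
#' @export
lorenzSeries <- function(sigma = 10, rho = 28, beta = 8 / 3, dt = 0.01, n,
                         burnTime = 10, state0 = c(1, 1, 1)) {
  stopifnot(dt > 0, dt <= 0.02, n >= 1)
  deriv <- function(s)
    c(sigma * (s[2L] - s[1L]),
      s[1L] * (rho - s[3L]) - s[2L],
      s[1L] * s[2L] - beta * s[3L])
  rk4 <- function(s) {
    k1 <- deriv(s)
    k2 <- deriv(s + dt / 2 * k1)
    k3 <- deriv(s + dt / 2 * k2)
    k4 <- deriv(s + dt * k3)
    s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s <- as.numeric(state0)
  for (k in seq_len(ceiling(burnTime / dt))) s <- rk4(s)
  xs <- numeric(n); ys <- numeric(n); zs <- numeric(n)
  for (k in seq_len(n)) {
    s <- rk4(s)
    xs[k] <- s[1L]; ys[k] <- s[2L]; zs[k] <- s[3L]
  }
  list(x = xs, y = ys, z = zs)
}

#' Seeded stochastic test series
#'
#' `whiteSeries` draws i.i.d. Gaussian noise; `arSeries` runs an AR
#' recursion with Gaussian innovations (a stationarity check rejects
#' explosive coefficient sets; empty `coeffs` reduces to white noise);
#' `sineMix` sums sinusoids of given frequencies and amplitudes, with
#' optional seeded random phases.
#'
#' @param sigma innovation / noise SD.
#' @param n output length.
#' @param seed integer seed.
#' @return Numeric series of length `n`.
#' @export
whiteSeries <- function(sigma = 1, n, seed = 1L) {
  stopifnot(sigma >= 0, n >= 1)
  withSeed(seed, rnorm(n, sd = sigma))
}

#' @rdname whiteSeries
#' @param coeffs AR coefficients `a_k` (convention
#'   `x_n = sum a_k x_{n-k} + w_n`).
#' @param burn burn-in samples discarded.
#' @export
arSeries <- function(coeffs, sigma = 1, n, seed = 1L, burn = 200L) {
  coeffs <- as.numeric(coeffs)
  p <- length(coeffs)
  if (p == 0L) return(whiteSeries(sigma, n, seed))
  roots <- polyroot(c(1, -coeffs))
  if (any(Mod(roots) <= 1 + 1e-10))
    stop("non-stationary AR coefficients: characteristic root on or inside the unit circle")
  total <- n + burn
  w <- withSeed(seed, rnorm(total, sd = sigma))
  x <- numeric(total)
  for (t in seq_len(total)) {
    acc <- w[t]
    for (k in seq_len(min(p, t - 1L)))
      acc <- acc + coeffs[k] * x[t - k]
    x[t] <- acc
  }
  x[(burn + 1L):total]
}

#' @rdname whiteSeries
#' @param freqs,amps sinusoid frequencies (Hz) and amplitudes.
#' @param fs sampling rate in Hz.
#' @param randomPhase draw phases uniformly (seeded)? Default `FALSE`
#'   (zero phases).
#' @export
sineMix <- function(freqs, amps, fs, n, seed = 1L, randomPhase = FALSE) {
  stopifnot(length(freqs) == length(amps), fs > 0, n >= 1)
  phases <- if (randomPhase)
    withSeed(seed, runif(length(freqs), 0, 2 * pi)) else
    rep(0, length(freqs))
  t <- seq_len(n) / fs
  out <- numeric(n)
  for (k in seq_along(freqs))
    out <- out + amps[k] * sin(2 * pi * freqs[k] * t + phases[k])
  out
}

#' Specification of one synthetic task class
#'
#' Parameter bundle describing how recordings of one mental-task class are
#' composed: relative alpha (8-13 Hz) and beta (14-30 Hz) band weights of
#' the shaped background noise, the weight of the chaotic (Lorenz) component,
#' an overall amplitude scale, and a low-pass smoothness cutoff in Hz.
#'
#' @param name class name; one of `relax`, `math`, `letter`, `rotate`,
#'   `count`.
#' @param alphaRelPower,betaRelPower relative band weights (>= 0).
#' @param chaosMix weight of the chaotic component in `[0, 1]`.
#' @param amplitudeScale overall amplitude multiplier.
#' @param smoothness low-pass cutoff in Hz.
#' @return List of class `"TaskClassSpec"`.
#' @seealso [defaultTaskSpecs()], [syntheticRecording()]
#' @export
taskClassSpec <- function(name, alphaRelPower = 2, betaRelPower = 1,
                          chaosMix = 0.3, amplitudeScale = 1,
                          smoothness = 45) {
  stopifnot(is.character(name), length(name) == 1L,
            alphaRelPower >= 0, betaRelPower >= 0,
            chaosMix >= 0, chaosMix <= 1,
            amplitudeScale > 0, smoothness > 0)
  structure(list(name = name, alphaRelPower = alphaRelPower,
                 betaRelPower = betaRelPower, chaosMix = chaosMix,
                 amplitudeScale = amplitudeScale, smoothness = smoothness),
            class = "TaskClassSpec")
}

#' Default five-task class specifications
#'
#' The five classes mirror the canonical mental-task battery (relaxation,
#' mental arithmetic, letter composition, object rotation, counting). The
#' arithmetic-type tasks (`math`, `count`) are low-complexity and
#' high-amplitude: smooth, strongly alpha-weighted, little chaotic content.
#' `rotate` is the highest-complexity class (broadband, strong chaotic
#' component), `relax` is the classical alpha-dominant resting pattern and
#' `letter` sits in between.
#'
#' @return Named list of five [taskClassSpec()] objects.
#' @export
defaultTaskSpecs <- function() {
  specs <- list(
    taskClassSpec("relax", alphaRelPower = 3.0, betaRelPower = 0.5,
                  chaosMix = 0.30, amplitudeScale = 1.0, smoothness = 40),
    taskClassSpec("math", alphaRelPower = 2.0, betaRelPower = 1.5,
                  chaosMix = 0.10, amplitudeScale = 2.0, smoothness = 20),
    taskClassSpec("letter", alphaRelPower = 1.5, betaRelPower = 1.0,
                  chaosMix = 0.35, amplitudeScale = 1.0, smoothness = 50),
    taskClassSpec("rotate", alphaRelPower = 0.8, betaRelPower = 2.0,
                  chaosMix = 0.50, amplitudeScale = 0.8, smoothness = 80),
    taskClassSpec("count", alphaRelPower = 2.5, betaRelPower = 0.8,
                  chaosMix = 0.15, amplitudeScale = 1.8, smoothness = 25))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

eegLeadNames <- c("C3", "C4", "P3", "P4", "O1", "O2")

# Spectrally shaped unit-SD noise: band weights on alpha/beta, 1/f power
# elsewhere, 4th-order low-pass rolloff above `cutoff`.
shapedNoise <- function(n, fs, alphaW, betaW, cutoff, seed) {
  w <- withSeed(seed, rnorm(n))
  W <- fft(w)
  freqs <- fs * (0:(n - 1)) / n
  freqs <- pmin(freqs, fs - freqs)        # two-sided, Hermitian-symmetric
  amp <- 1 / sqrt(pmax(freqs, 1))         # 1/f power baseline
  amp[freqs >= 8 & freqs <= 13] <- sqrt(alphaW)
  amp[freqs >= 14 & freqs <= 30] <- sqrt(betaW)
  amp <- amp / sqrt(1 + (freqs / cutoff)^8)
  amp[1L] <- 0                            # remove DC
  y <- Re(fft(W * amp, inverse = TRUE)) / n
  (y - mean(y)) / sd(y)
}

#' Generate one synthetic multichannel recording
#'
#' Emulates a 7-lead, 250 Hz, 10 s recording of one task class. Each EEG
#' lead is `amplitudeScale * ((1 - chaosMix) * noise + chaosMix * lorenz)`,
#' where `noise` is unit-SD spectrally shaped background (class band
#' weights on 8-13 and 14-30 Hz, `1/f` elsewhere, low-passed at the class
#' smoothness cutoff) and `lorenz` is the z-scored x-trace of a Lorenz flow
#' sampled at `1/fs`, phase-offset per lead. The EOG lead is low-frequency
#' (< 4 Hz) noise, and leaks into the EEG leads with a coefficient that
#' decreases from frontal-central to occipital leads, so EOG-correlation
#' lead ranking has structure to find. Every noise stream is seeded per
#' lead; the generator is a pure function of its arguments.
#'
#' @param spec a [taskClassSpec()].
#' @param fs sampling rate in Hz (default 250).
#' @param durationS duration in seconds (default 10).
#' @param seed integer seed.
#' @param eogLeakage base EOG leakage amplitude into the EEG leads
#'   (default 0.15; 0 disables leakage).
#' @return A [Recording-class] with leads C3, C4, P3, P4, O1, O2, EOG.
#' @export
syntheticRecording <- function(spec, fs = 250, durationS = 10, seed = 1L,
                               eogLeakage = 0.15) {
  stopifnot(inherits(spec, "TaskClassSpec"))
  n <- as.integer(round(fs * durationS))
  seeds <- deriveSeeds(seed, length(eegLeadNames) + 1L)
  offset <- 50L
  lor <- lorenzSeries(dt = 1 / fs,
                      n = n + offset * (length(eegLeadNames) - 1L))$x
  lor <- (lor - mean(lor)) / sd(lor)
  eog <- shapedNoise(n, fs, alphaW = 0, betaW = 0, cutoff = 4,
                     seed = seeds[length(seeds)]) * 2
  leak <- eogLeakage * c(1, 0.9, 0.7, 0.6, 0.4, 0.3)
  samples <- matrix(0, nrow = length(eegLeadNames) + 1L, ncol = n)
  for (i in seq_along(eegLeadNames)) {
    noise <- shapedNoise(n, fs, spec$alphaRelPower, spec$betaRelPower,
                         spec$smoothness, seed = seeds[i])
    chaos <- lor[seq.int((i - 1L) * offset + 1L, length.out = n)]
    samples[i, ] <- spec$amplitudeScale *
      ((1 - spec$chaosMix) * noise + spec$chaosMix * chaos) +
      leak[i] * eog
  }
  samples[length(eegLeadNames) + 1L, ] <- eog
  Recording(samples, fs = fs, leadLabels = c(eegLeadNames, "EOG"),
            meta = sprintf("synthetic %s (seed %d)", spec$name, seed))
}

#' Generate a labelled synthetic dataset
#'
#' `nPerClass` recordings per task class, each from a distinct derived
#' seed, shuffled into random order with labels retained. The same parent
#' seed reproduces the dataset bit-wise.
#'
#' @param specs list of [taskClassSpec()] objects with distinct names
#'   (default [defaultTaskSpecs()]).
#' @param nPerClass recordings per class (>= 1).
#' @param fs,durationS recording shape.
#' @param seed parent seed.
#' @param eogLeakage passed to [syntheticRecording()].
#' @return List of class `"LabeledDataset"`: `recordings` (list of
#'   [Recording-class]), `labels`, `classOrder`, `seed`.
#' @examples
#' ds <- syntheticDataset(nPerClass = 2, seed = 42)
#' table(ds$labels)
#' @export
syntheticDataset <- function(specs = defaultTaskSpecs(), nPerClass = 20L,
                             fs = 250, durationS = 10, seed = 42L,
                             eogLeakage = 0.15) {
  stopifnot(nPerClass >= 1L)
  classNames <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(classNames))
    stop("duplicate class names in specs")
  total <- length(specs) * nPerClass
  seeds <- deriveSeeds(seed, total)
  recordings <- vector("list", total)
  labels <- character(total)
  k <- 0L
  for (sp in specs) {
    for (j in seq_len(nPerClass)) {
      k <- k + 1L
      recordings[[k]] <- syntheticRecording(sp, fs = fs,
                                            durationS = durationS,
                                            seed = seeds[k],
                                            eogLeakage = eogLeakage)
      labels[k] <- sp$name
    }
  }
  ord <- withSeed(seed, sample.int(total))
  structure(list(recordings = recordings[ord], labels = labels[ord],
                 classOrder = unname(classNames), seed = as.integer(seed)),
            class = "LabeledDataset")
}

#' @export
print.LabeledDataset <- function(x, ...) {
  cat(sprintf("LabeledDataset: %d recordings, %d classes (seed %d)\n",
              length(x$recordings), length(x$classOrder), x$seed))
  print(table(x$labels))
  invisible(x)
}
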