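#' Tangent-vector angle-cosine series
#'
#' For a phase-space trajectory, forms the tangent vectors
#' `T_n = X_{n+1} - X_n` and returns the series of cosines of the angles
#' between consecutive tangents,
#' `A(n) = (T_n . T_{n+1}) / (||T_n|| ||T_{n+1}||)`. The cosine is used
#' rather than the angle itself because it is less noise-sensitive. Pairs
#' involving a zero-length tangent (repeated identical points) are skipped
#' with a message; if every pair is degenerate an error is raised.
#'
#' @param traj an [EmbeddedTrajectory-class] with at least 3 points.
#' @return Numeric series of length at most `M - 2`, values in `[-1, 1]`.
#' @seealso [sodp()], [ctm()]
#' @export
tangentAngleSeries <- function(traj) {
  stopifnot(is(traj, "EmbeddedTrajectory"))
  pts <- traj@points
  M <- nrow(pts)
  if (M < 3L) stop("trajectory must have at least 3 points")
  tv <- pts[-1L, , drop = FALSE] - pts[-M, , drop = FALSE]
  nrm <- sqrt(rowSums(tv^2))
  dots <- rowSums(tv[-nrow(tv), , drop = FALSE] * tv[-1L, , drop = FALSE])
  denom <- nrm[-length(nrm)] * nrm[-1L]
  ok <- denom > 0
  if (!any(ok))
    stop("all tangent pairs are degenerate (repeated identical points)")
  if (!all(ok))
    message(sprintf("tangentAngleSeries: skipped %d degenerate tangent pair(s)",
                    sum(!ok)))
  a <- dots[ok] / denom[ok]
  pmin(1, pmax(-1, a))
}

#' Second-order difference plot of a series
#'
#' Scatter of successive differences: point `n` is
#' `(A(n+2) - A(n+1), A(n+1) - A(n))`, describing the change rate of the
#' underlying series (here, the tangent-angle cosines).
#'
#' @param a numeric series (length >= 3).
#' @return List of class `"SODP"` with `points` (an `(n-2) x 2` matrix) and
#'   `sourceLength`.
#' @export
sodp <- function(a) {
  a <- as.numeric(a)
  n <- length(a)
  if (n < 3L) stop("need at least 3 values to form an SODP")
  pts <- cbind(u = a[3:n] - a[2:(n - 1L)], v = a[2:(n - 1L)] - a[1:(n - 2L)])
  structure(list(points = pts, sourceLength = n), class = "SODP")
}

#' @export
print.SODP <- function(x, ...) {
  cat(sprintf("SODP: %d points from a series of length %d\n",
              nrow(x$points), x$sourceLength))
  invisible(x)
}

#' Central tendency measure
#'
#' Fraction of SODP points whose Euclidean norm is strictly less than
#' `radius`. A smooth trajectory has small second differences of its
#' tangent-angle series, so its SODP concentrates near the origin and its
#' CTM is large; a rough (random-like) trajectory has a small CTM.
#'
#' @param sodp an object from [sodp()].
#' @param radius positive radius around the SODP origin.
#' @return Fraction in `[0, 1]`.
#' @export
ctm <- function(sodp, radius) {
  stopifnot(inherits(sodp, "SODP"))
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("radius must be a single positive number")
  norms <- sqrt(rowSums(sodp$points^2))
  mean(norms < radius)
}

#' One IAAFT surrogate of a series
#'
#' Iterative amplitude-adjusted Fourier transform: starting from a seeded
#' random permutation of `x`, alternately (i) impose the original Fourier
#' amplitude spectrum while keeping the current phases, and (ii) rank-remap
#' the result onto the original sorted amplitudes, for `nIter` iterations
#' (ending with the rank-remap, so the amplitude multiset of the surrogate
#' equals that of `x` exactly). The surrogate approximates the linear
#' stochastic null: same amplitude distribution, autocorrelation and power
#' spectrum, randomised phases.
#'
#' @param x numeric series (length >= 16, non-constant).
#' @param nIter number of IAAFT iterations.
#' @param seed integer seed.
#' @param returnTrace also return the per-iteration relative L2 deviation of
#'   the surrogate amplitude spectrum from the original (as attribute
#'   `"spectralError"`)?
#' @return Numeric series of the same length as `x`.
#' @export
iaaftSurrogate <- function(x, nIter = 100L, seed = 1L, returnTrace = FALSE) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= 16L, nIter >= 1L)
  if (sd(x) == 0)
    stop("degenerate input: constant series has no nontrivial surrogate")
  amp <- Mod(fft(x))
  ampRef <- sqrt(sum(amp^2))
  sortedX <- sort(x)
  trace <- if (returnTrace) numeric(nIter) else NULL
  y <- withSeed(seed, sample(x))
  for (it in seq_len(nIter)) {
    Y <- fft(y)
    modY <- Mod(Y)
    modY[modY == 0] <- 1            # undefined phase at zero bins: keep 0/1
    z <- Re(fft(amp * Y / modY, inverse = TRUE)) / n
    # rank-remap onto the original sorted amplitudes
    y <- numeric(n)
    y[order(z)] <- sortedX
    if (returnTrace)
      trace[it] <- sqrt(sum((Mod(fft(y)) - amp)^2)) / ampRef
  }
  if (returnTrace) attr(y, "spectralError") <- trace
  y
}

#' An ensemble of IAAFT surrogates
#'
#' @param x numeric series.
#' @param n number of surrogates; the default 19 follows the one-sided
#'   rank-test convention.
#' @param nIter IAAFT iterations per surrogate.
#' @param seed parent seed; each surrogate uses a distinct derived stream.
#' @return A [SurrogateEnsemble-class].
#' @export
surrogateEnsemble <- function(x, n = 19L, nIter = 100L, seed = 1L) {
  seeds <- deriveSeeds(seed, n)
  surr <- lapply(seeds, function(s) iaaftSurrogate(x, nIter = nIter, seed = s))
  new("SurrogateEnsemble", surrogates = surr, nIter = as.integer(nIter),
      seed = as.integer(seed))
}

#' Surrogate-data determinism test via CTM
#'
#' Embeds the series, computes the CTM of the SODP of its tangent-angle
#' cosines, repeats the computation for an IAAFT surrogate ensemble with the
#' same radius, and forms the determinism ratio
#' `S = (1 - CTM_data) / (1 - mean CTM_surrogate)`, clipped at 0.
#' The radius is `ctm_radius_factor` times the SD of the data's SODP point
#' norms. A deterministic signal is smoother than its linear-stochastic
#' surrogates (larger CTM), giving `S` well below 1; a purely stochastic
#' signal is statistically identical to its surrogates, giving `S` near 1.
#' Classification uses the conventional thresholds: `S < 0.3` deterministic,
#' `0.3 <= S <= 0.7` partly deterministic, `S > 0.7` random.
#'
#' Note on orientation: CTM here is the fraction of SODP points *inside* the
#' radius, so larger CTM means a smoother trajectory; `S` is defined on
#' `1 - CTM` so the thresholds above keep their usual meaning.
#'
#' @param x numeric series.
#' @param cfg an [analysisConfig()].
#' @param ensemble optionally, a precomputed [SurrogateEnsemble-class] (or
#'   list of series) to test against instead of freshly generated IAAFT
#'   surrogates.
#' @return List of class `"DeterminismResult"`: `ctm_data`,
#'   `ctm_surrogate_mean`, `S`, `classification`, `radius`.
#' @examples
#' x <- logisticSeries(4, 0.2, 500)
#' determinismRatio(x, analysisConfig(m_embed = 4, n_surrogates = 5,
#'                                    surrogate_iters = 30))
#' @export
determinismRatio <- function(x, cfg = analysisConfig(), ensemble = NULL) {
  x <- as.numeric(x)
  validateConfig(cfg)
  ctmOf <- function(series, radius) {
    a <- tangentAngleSeries(delayEmbed(series, cfg$m_embed, cfg$tau))
    ctm(sodp(a), radius)
  }
  aData <- tangentAngleSeries(delayEmbed(x, cfg$m_embed, cfg$tau))
  sd0 <- sodp(aData)
  norms <- sqrt(rowSums(sd0$points^2))
  radius <- cfg$ctm_radius_factor * sd(norms)
  if (!is.finite(radius) || radius <= 0)
    stop("degenerate input: SODP point norms have zero spread")
  ctmData <- ctm(sd0, radius)
  surr <- if (is.null(ensemble)) {
    surrogates(surrogateEnsemble(x, n = cfg$n_surrogates,
                                 nIter = cfg$surrogate_iters,
                                 seed = cfg$seed))
  } else if (is(ensemble, "SurrogateEnsemble")) {
    surrogates(ensemble)
  } else ensemble
  ctmSurr <- vapply(surr, ctmOf, numeric(1), radius = radius)
  ctmSurrMean <- mean(ctmSurr)
  num <- 1 - ctmData
  den <- 1 - ctmSurrMean
  S <- if (den == 0) {
    if (num == 0) 1 else Inf
  } else max(0, num / den)
  cls <- if (S < 0.3) "deterministic"
         else if (S > 0.7) "random"
         else "partly-deterministic"
  structure(list(ctm_data = ctmData, ctm_surrogate_mean = ctmSurrMean,
                 S = S, classification = cls, radius = radius),
            class = "DeterminismResult")
}

#' @export
print.DeterminismResult <- function(x, ...) {
  cat(sprintf(
    "Determinism test: CTM(data) = %.4f, CTM(surrogates) = %.4f\n",
    x$ctm_data, x$ctm_surrogate_mean))
  cat(sprintf("  S = %.4f -> %s\n", x$S, x$classification))
  invisible(x)
}
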