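#' Delay-coordinate embedding
#'
#' Reconstructs an `m`-dimensional phase-space trajectory from a scalar
#' series by the method of delays: point `i` is
#' `(x_i, x_{i+tau}, ..., x_{i+(m-1)tau})`, giving `M = N - (m-1)*tau`
#' points. Forward indexing is used consistently throughout the package.
#'
#' @param x numeric series of length `N`.
#' @param m embedding dimension (>= 1; `m = 1` returns the series itself).
#' @param tau delay in samples (>= 1).
#' @return An [EmbeddedTrajectory-class].
#' @examples
#' delayEmbed(1:10, m = 3, tau = 2)
#' @export
delayEmbed <- function(x, m, tau) {
  x <- as.numeric(x)
  n <- length(x)
  m <- as.integer(m); tau <- as.integer(tau)
  stopifnot(m >= 1L, tau >= 1L)
  M <- n - (m - 1L) * tau
  if (M < 1L)
    stop(sprintf(
      "series too short: N = %d gives M = %d points for m = %d, tau = %d",
      n, M, m, tau))
  pts <- matrix(0, nrow = M, ncol = m)
  for (k in seq_len(m))
    pts[, k] <- x[seq.int(1L + (k - 1L) * tau, length.out = M)]
  new("EmbeddedTrajectory", points = pts, m = m, tau = tau,
      sourceN = n)
}

#' Multi-lead (multivariable) embedding
#'
#' Takes each selected lead as one coordinate of the state vector, so the
#' embedding dimension equals the number of leads and every time point
#' becomes a phase-space point (`M = N`, delay recorded as 0). This spatial
#' reconstruction avoids the delay-parameter choice of scalar embeddings.
#'
#' @param rec a [Recording-class].
#' @param leads ordered character vector of at least two lead names.
#' @return An [EmbeddedTrajectory-class].
#' @export
multileadEmbed <- function(rec, leads) {
  stopifnot(is(rec, "Recording"), length(leads) >= 2L)
  missing <- setdiff(leads, rec@leadLabels)
  if (length(missing))
    stop(sprintf("unknown lead(s): %s", paste(missing, collapse = ", ")))
  pts <- t(rec@samples[leads, , drop = FALSE])
  dimnames(pts) <- NULL
  new("EmbeddedTrajectory", points = pts, m = length(leads), tau = 0L,
      sourceN = ncol(rec@samples))
}

#' Splice several leads into one long series
#'
#' Concatenates the selected leads in order. By default each lead is
#' z-scored before concatenation so that inter-lead amplitude offsets do not
#' create artificial jumps at the splice joints; set `normalize = FALSE` for
#' raw concatenation. The splice-joint positions are returned as the
#' `"joints"` attribute (index of the last sample of each non-final segment)
#' so that downstream embeddings can mask points straddling a joint.
#'
#' @param rec a [Recording-class].
#' @param leads ordered character vector of lead names (>= 1).
#' @param normalize z-score each lead before concatenation?
#' @return Numeric series of length `length(leads) * N`, with attribute
#'   `"joints"`.
#' @export
spliceLeads <- function(rec, leads, normalize = TRUE) {
  stopifnot(is(rec, "Recording"), length(leads) >= 1L)
  missing <- setdiff(leads, rec@leadLabels)
  if (length(missing))
    stop(sprintf("unknown lead(s): %s", paste(missing, collapse = ", ")))
  n <- nSamples(rec)
  segs <- lapply(leads, function(ld) {
    v <- getLead(rec, ld)
    if (normalize) {
      s <- sd(v)
      if (s == 0) stop(sprintf("lead '%s' is constant; cannot z-score", ld))
      v <- (v - mean(v)) / s
    }
    v
  })
  out <- unlist(segs, use.names = FALSE)
  joints <- if (length(leads) > 1L)
    n * seq_len(length(leads) - 1L) else integer()
  attr(out, "joints") <- joints
  out
}

#' Mean period of a series
#'
#' Average oscillation cycle length in samples, computed as the sampling
#' rate divided by the power-weighted mean frequency of the raw periodogram
#' (DC excluded), rounded up to an integer >= 1. Used as the temporal
#' exclusion window in the Lyapunov nearest-neighbour search and as the
#' default Theiler window.
#'
#' @param x numeric series (length >= 16).
#' @param fs sampling rate in Hz (use 1 for maps).
#' @return Integer period in samples.
#' @examples
#' t <- seq(0, 10, by = 1 / 250)[-1]
#' meanPeriod(sin(2 * pi * 10 * t), fs = 250)  # 25 samples
#' @export
meanPeriod <- function(x, fs) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= 16L, fs > 0)
  x <- x - mean(x)
  X <- fft(x)
  nf <- floor(n / 2)
  pw <- Mod(X[2:(nf + 1L)])^2      # positive frequencies, DC excluded
  freqs <- fs * seq_len(nf) / n
  tot <- sum(pw)
  if (tot <= 0 || !is.finite(tot))
    stop("degenerate input: series has no nonzero-frequency power")
  fbar <- sum(freqs * pw) / tot
  max(1L, as.integer(ceiling(fs / fbar)))
}
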