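#' Nearest phase-space neighbours under temporal exclusion
#'
#' For each trajectory point `X_j`, finds the nearest (Euclidean) point
#' `X_jhat` whose temporal separation exceeds `minSep` samples — the
#' Rosenstein prescription uses the mean period, so the neighbour lies on a
#' different orbit rather than just ahead on the same one. Ties break to the
#' smaller index; points with no admissible neighbour get `NA` and are
#' excluded downstream.
#'
#' @param traj an [EmbeddedTrajectory-class].
#' @param minSep temporal exclusion in samples (neighbours must satisfy
#'   `|i - j| > minSep`).
#' @param valid optional logical mask of usable points (used to mask splice
#'   joints); defaults to all points.
#' @return List of class `"NNPairs"`: `nn` (integer neighbour index or NA),
#'   `dist`, `minSep`.
#' @export
nearestNeighborPairs <- function(traj, minSep, valid = NULL) {
  stopifnot(is(traj, "EmbeddedTrajectory"))
  M <- nPoints(traj)
  minSep <- as.integer(minSep)
  if (is.null(valid)) valid <- rep(TRUE, M)
  stopifnot(length(valid) == M)
  res <- .nnPairs(traj@points, minSep, valid)
  nn <- res$nn
  nn[nn == 0L] <- NA_integer_
  if (all(is.na(nn)))
    stop(sprintf(
      "no admissible neighbour for any point (M = %d, minSep = %d)",
      M, minSep))
  structure(list(nn = nn, dist = res$dist, minSep = minSep),
            class = "NNPairs")
}

#' Mean log-divergence curve of neighbour pairs
#'
#' Advances every neighbour pair `(j, jhat)` along the trajectory and
#' records `y(i) = < ln || X_{j+i} - X_{jhat+i} || >`, the mean log distance
#' at step `i` over the pairs still inside the trajectory. Under chaotic
#' dynamics the nearby orbits separate as `d_j(i) ~ d_j(0) e^{lambda1 i dt}`,
#' so the early part of `y(i)` is a straight line with slope
#' `lambda1 * dt`. Pairs at exactly zero distance at a step are dropped from
#' that step's mean (reported in `zero_dropped`) rather than floored.
#'
#' @param traj an [EmbeddedTrajectory-class].
#' @param pairs an `"NNPairs"` from [nearestNeighborPairs()].
#' @param maxSteps largest advance step.
#' @param dt seconds per step (1 for maps).
#' @param valid optional logical mask of usable points.
#' @return List of class `"DivergenceCurve"`: `steps` (0..maxSteps), `y`,
#'   `n_pairs`, `dt`, `zero_dropped`.
#' @export
divergenceCurve <- function(traj, pairs, maxSteps, dt = 1, valid = NULL) {
  stopifnot(is(traj, "EmbeddedTrajectory"), inherits(pairs, "NNPairs"))
  M <- nPoints(traj)
  if (is.null(valid)) valid <- rep(TRUE, M)
  maxSteps <- min(as.integer(maxSteps), M - 1L)
  nn <- pairs$nn
  nn[is.na(nn)] <- 0L
  res <- .divergenceCurve(traj@points, nn, maxSteps, valid)
  if (res$n_pairs[1L] == 0L)
    stop("no surviving neighbour pairs at step 0")
  structure(list(steps = 0:maxSteps, y = res$y, n_pairs = res$n_pairs,
                 dt = dt, zero_dropped = res$zero_dropped),
            class = "DivergenceCurve")
}

#' @export
print.DivergenceCurve <- function(x, ...) {
  cat(sprintf(
    "DivergenceCurve: %d steps (dt = %g s), %d pairs at step 0\n",
    length(x$steps) - 1L, x$dt, x$n_pairs[1L]))
  invisible(x)
}

#' @export
plot.DivergenceCurve <- function(x, ...) {
  graphics::plot(x$steps * x$dt, x$y, type = "l", xlab = "time (s)",
                 ylab = "< ln d(i) >", ...)
  invisible(x)
}

#' Largest Lyapunov exponent from a divergence curve
#'
#' Least-squares slope of `y(i)` against `i * dt` over the fit window
#' `[fitLo, fitHi]` (step values), giving `lambda1` per unit time (per
#' iteration when `dt = 1`). The window must contain at least 4 steps with
#' surviving pairs.
#'
#' @param curve a `"DivergenceCurve"`.
#' @param fitLo,fitHi first and last step of the fit window.
#' @return `lambda1` (scalar).
#' @export
maxLyapunov <- function(curve, fitLo, fitHi) {
  stopifnot(inherits(curve, "DivergenceCurve"))
  if (fitLo < min(curve$steps) || fitHi > max(curve$steps) || fitLo > fitHi)
    stop(sprintf("fit window [%d, %d] outside curve steps [%d, %d]",
                 fitLo, fitHi, min(curve$steps), max(curve$steps)))
  sel <- curve$steps >= fitLo & curve$steps <= fitHi &
    curve$n_pairs > 0 & is.finite(curve$y)
  if (sum(sel) < 4L)
    stop("fit window must contain at least 4 steps with surviving pairs")
  t <- curve$steps[sel] * curve$dt
  unname(coef(lm(curve$y[sel] ~ t))[2L])
}

newNoFitWindowCondition <- function(msg) {
  structure(class = c("noFitWindowError", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

#' Automatic fit-window selection for the divergence curve
#'
#' Scans the step-to-step slopes of `y(i)` for the longest contiguous run
#' (of at least `minLen` steps) whose local slopes are positive and stay
#' within a relative fluctuation `tol` of their run mean; the earliest such
#' run wins ties. A curve that saturates immediately (stochastic input) has
#' no stable positive-slope run and raises a `noFitWindowError`.
#'
#' @param curve a `"DivergenceCurve"`.
#' @param tol relative slope-stability tolerance (default 20%).
#' @param minLen minimum run length in steps.
#' @return `c(fitLo, fitHi)` step values.
#' @export
autoFitWindow <- function(curve, tol = 0.2, minLen = 4L) {
  stopifnot(inherits(curve, "DivergenceCurve"))
  ok <- curve$n_pairs > 0 & is.finite(curve$y)
  steps <- curve$steps[ok]
  y <- curve$y[ok]
  if (length(y) < minLen + 1L)
    stop(newNoFitWindowCondition("divergence curve too short"))
  s <- diff(y) / diff(steps)
  n <- length(s)
  best <- NULL
  for (a in seq_len(n - minLen + 1L)) {
    for (b in (a + minLen - 1L):n) {
      seg <- s[a:b]
      mu <- mean(seg)
      if (mu <= 0) break
      if (max(abs(seg - mu)) / mu >= tol) break
      len <- b - a + 1L
      if (is.null(best) || len > best$len)
        best <- list(a = a, b = b, len = len)
    }
  }
  if (is.null(best))
    stop(newNoFitWindowCondition(
      "no stable positive-slope fit window: divergence curve saturates or fluctuates"))
  c(steps[best$a], steps[best$b + 1L])
}

#' Largest Lyapunov exponent of a scalar series
#'
#' Convenience composition of [delayEmbed()], [nearestNeighborPairs()],
#' [divergenceCurve()] and [maxLyapunov()].
#'
#' @param x numeric series.
#' @param m,tau embedding parameters.
#' @param fs sampling rate in Hz (1 for maps; `dt = 1/fs`).
#' @param minSep temporal exclusion; default: the mean period of `x`.
#' @param maxSteps divergence-curve length; default `max(30, 3 * minSep)`.
#' @param fitLo,fitHi fit window in steps; `NULL` for [autoFitWindow()].
#' @return `lambda1` per second (per iteration when `fs = 1`), with the
#'   curve and window attached as attributes `"curve"` and `"window"`.
#' @examples
#' x <- logisticSeries(4, 0.2, 3000)
#' lyapunovExponent(x, m = 2, tau = 1, minSep = 10, fitLo = 1, fitHi = 8)
#' @export
lyapunovExponent <- function(x, m, tau, fs = 1, minSep = NULL,
                             maxSteps = NULL, fitLo = NULL, fitHi = NULL) {
  x <- as.numeric(x)
  if (is.null(minSep)) minSep <- meanPeriod(x, fs = fs)
  if (is.null(maxSteps)) maxSteps <- max(30L, 3L * as.integer(minSep))
  traj <- delayEmbed(x, m, tau)
  pairs <- nearestNeighborPairs(traj, minSep)
  curve <- divergenceCurve(traj, pairs, maxSteps = maxSteps, dt = 1 / fs)
  if (is.null(fitLo) || is.null(fitHi)) {
    win <- autoFitWindow(curve)
    fitLo <- win[1L]; fitHi <- win[2L]
  }
  lam <- maxLyapunov(curve, fitLo, fitHi)
  attr(lam, "curve") <- curve
  attr(lam, "window") <- c(fitLo, fitHi)
  lam
}

#' Largest Lyapunov exponent of a multichannel recording
#'
#' Splices the selected leads (z-scored) into one series, delay-embeds it
#' with `cfg$tau` and `cfg$m_embed`, masks embedding windows that straddle a
#' splice joint from the neighbour search, uses the mean period of the
#' splice as temporal exclusion, auto-selects the fit window by the
#' slope-stability rule, and returns `lambda1` in 1/seconds
#' (`dt = 1/fs`). A recording without exponential divergence (e.g. i.i.d.
#' noise, whose curve saturates immediately) raises a `noFitWindowError`.
#'
#' @param rec a [Recording-class].
#' @param cfg an [analysisConfig()].
#' @param leads leads to splice; default: the 3 least-EOG-correlated leads
#'   (all non-EOG leads if fewer).
#' @return `lambda1` per second, with attributes `"curve"` and `"window"`.
#' @export
lyapunovFromRecording <- function(rec, cfg = analysisConfig(), leads = NULL) {
  stopifnot(is(rec, "Recording"))
  if (is.null(leads)) {
    leads <- if ("EOG" %in% leadLabels(rec))
      head(rankLeadsByEOG(rec), 3L) else leadLabels(rec)
  }
  x <- spliceLeads(rec, leads, normalize = TRUE)
  joints <- attr(x, "joints")
  fs <- samplingRate(rec)
  traj <- delayEmbed(as.numeric(x), cfg$m_embed, cfg$tau)
  M <- nPoints(traj)
  span <- (cfg$m_embed - 1L) * cfg$tau
  valid <- rep(TRUE, M)
  for (j in joints) {
    # mask embedding windows [i, i + span] that contain the joint boundary
    lo <- max(1L, j - span + 1L)
    hi <- min(M, j)
    if (lo <= hi) valid[lo:hi] <- FALSE
  }
  minSep <- meanPeriod(as.numeric(x), fs = fs)
  pairs <- nearestNeighborPairs(traj, minSep, valid = valid)
  maxSteps <- max(30L, 3L * minSep)
  curve <- divergenceCurve(traj, pairs, maxSteps = maxSteps, dt = 1 / fs,
                           valid = valid)
  win <- autoFitWindow(curve)
  lam <- maxLyapunov(curve, win[1L], win[2L])
  attr(lam, "curve") <- curve
  attr(lam, "window") <- win
  lam
}
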