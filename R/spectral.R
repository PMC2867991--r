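#' Burg autoregressive model fit
#'
#' Estimates an AR(p) model by Burg's method: at each stage the reflection
#' coefficient minimises the summed forward and backward prediction-error
#' energy under the Levinson recursion constraint, which guarantees
#' `|kappa_k| < 1` and hence a stable model without computing the
#' autocorrelation function. The coefficient convention is
#' `x_n = sum_k a_k x_{n-k} + w_n`, so for an AR(1) with parameter 0.9 the
#' fitted `a_1` is close to +0.9.
#'
#' @param x numeric series of length `N > 2p`.
#' @param p model order (>= 0; `p = 0` returns no coefficients and
#'   `sigma2 = mean(x^2)`).
#' @return List of class `"ARModel"`: `order`, `coefficients` (`a_k`),
#'   `sigma2` (residual variance), `reflection` (`kappa_k`),
#'   `sigma2_by_order` (residual variance after each stage `0..p`), `n`.
#' @examples
#' x <- arSeries(0.9, sigma = 1, n = 2000, seed = 1)
#' burgFit(x, 1)$coefficients
#' @export
burgFit <- function(x, p) {
  x <- as.numeric(x)
  n <- length(x)
  p <- as.integer(p)
  stopifnot(p >= 0L)
  if (p > 0L && p >= n / 2)
    stop(sprintf("order p = %d too large for N = %d (need p < N/2)", p, n))
  if (n < 2L || sd(x) == 0)
    stop("degenerate input: constant (or too short) series")
  e <- mean(x^2)
  sigma2ByOrder <- numeric(p + 1L)
  sigma2ByOrder[1L] <- e
  a <- numeric(0)        # polynomial coefficients, convention 1 + sum A_k z^-k
  kappa <- numeric(p)
  f <- x                 # forward prediction error
  b <- x                 # backward prediction error
  if (p > 0L) {
    for (k in seq_len(p)) {
      len <- length(f)
      fk <- f[2:len]
      bk <- b[1:(len - 1L)]
      den <- sum(fk^2) + sum(bk^2)
      kk <- if (den == 0) 0 else -2 * sum(fk * bk) / den
      kappa[k] <- kk
      fNew <- fk + kk * bk
      bNew <- bk + kk * fk
      f <- fNew
      b <- bNew
      a <- if (k == 1L) kk else c(a + kk * rev(a), kk)
      e <- e * (1 - kk^2)
      sigma2ByOrder[k + 1L] <- e
    }
  }
  structure(list(order = p, coefficients = -a, sigma2 = e,
                 reflection = kappa, sigma2_by_order = sigma2ByOrder,
                 n = n),
            class = "ARModel")
}

#' Construct an AR model directly
#'
#' Builds an `"ARModel"` from known coefficients, e.g. to evaluate the
#' closed-form spectrum of a theoretical process with [arPSD()].
#'
#' @param coefficients `a_k` in the convention
#'   `x_n = sum_k a_k x_{n-k} + w_n`.
#' @param sigma2 innovation variance.
#' @param n nominal fit length (metadata only).
#' @return An `"ARModel"`.
#' @export
arModel <- function(coefficients, sigma2 = 1, n = NA_integer_) {
  coefficients <- as.numeric(coefficients)
  stopifnot(sigma2 >= 0, all(is.finite(coefficients)))
  p <- length(coefficients)
  structure(list(order = p, coefficients = coefficients, sigma2 = sigma2,
                 reflection = numeric(0),
                 sigma2_by_order = rep(NA_real_, p + 1L), n = n),
            class = "ARModel")
}

#' @export
print.ARModel <- function(x, ...) {
  cat(sprintf("Burg AR(%d) model (N = %d): sigma2 = %.5g\n",
              x$order, x$n, x$sigma2))
  if (x$order > 0L)
    cat("  a:", paste(sprintf("%.4f", x$coefficients), collapse = ", "), "\n")
  invisible(x)
}

#' AIC model-order selection for Burg AR fits
#'
#' Selects `argmin_p N * ln(sigma2_hat(p)) + 2p` over `p = 0..pMax`, using
#' the forecasting-error power from a single Burg recursion run to `pMax`;
#' exact ties go to the smaller order.
#'
#' @param x numeric series.
#' @param pMax largest candidate order (`< N/2`).
#' @return Selected order (integer), with the AIC values for `0..pMax` as
#'   attribute `"aic"`.
#' @export
aicOrder <- function(x, pMax) {
  x <- as.numeric(x)
  n <- length(x)
  pMax <- as.integer(pMax)
  fit <- burgFit(x, pMax)
  aic <- n * log(fit$sigma2_by_order) + 2 * (0:pMax)
  sel <- which.min(aic) - 1L
  structure(sel, aic = aic)
}

#' AR power spectral density
#'
#' Evaluates `P(f) = sigma2 * dt / |1 - sum_k a_k exp(-i 2 pi f k dt)|^2`
#' on the uniform grid `f_k = k * fs / nfft`, `k = 0..nfft/2`. The value is
#' the two-sided density evaluated on non-negative frequencies (a white
#' noise model of unit variance gives the constant `1/fs`); integrals over
#' the full `[-fs/2, fs/2]` band therefore recover the series variance.
#'
#' @param model an `"ARModel"` from [burgFit()].
#' @param fs sampling rate in Hz.
#' @param nfft FFT length (>= `2 * order`); defaults to 1024.
#' @return List of class `"SpectralEstimate"`: `frequencies`, `psd`,
#'   `nfft`, `fs`.
#' @export
arPSD <- function(model, fs, nfft = 1024L) {
  stopifnot(inherits(model, "ARModel"), fs > 0)
  nfft <- as.integer(nfft)
  if (nfft < 2L * model$order)
    stop(sprintf("nfft = %d too small for order %d", nfft, model$order))
  poly <- c(1, -model$coefficients)
  A <- fft(c(poly, rep(0, nfft - length(poly))))
  half <- A[1:(nfft %/% 2L + 1L)]
  psd <- model$sigma2 / fs / Mod(half)^2
  structure(list(frequencies = (0:(nfft %/% 2L)) * fs / nfft, psd = psd,
                 nfft = nfft, fs = fs),
            class = "SpectralEstimate")
}

#' @export
print.SpectralEstimate <- function(x, ...) {
  cat(sprintf("SpectralEstimate: %d frequencies, 0..%g Hz (nfft = %d)\n",
              length(x$frequencies), max(x$frequencies), x$nfft))
  invisible(x)
}

#' @export
plot.SpectralEstimate <- function(x, log = "y", ...) {
  graphics::plot(x$frequencies, x$psd, type = "l", log = log,
                 xlab = "frequency (Hz)", ylab = "PSD", ...)
  invisible(x)
}

#' Band energy of a spectral estimate
#'
#' Trapezoidal integral of the PSD over `[lo, hi]` Hz; band edges that fall
#' between grid points are linearly interpolated, so disjoint bands tiling
#' `[0, fs/2]` sum exactly to the total integral.
#'
#' @param spec a `"SpectralEstimate"`.
#' @param lo,hi band limits in Hz, `0 <= lo < hi <= fs/2`.
#' @return Non-negative scalar.
#' @export
bandEnergy <- function(spec, lo, hi) {
  stopifnot(inherits(spec, "SpectralEstimate"))
  ny <- spec$fs / 2
  if (lo < 0 || hi > ny + 1e-9 || lo >= hi)
    stop(sprintf("band [%g, %g] outside the Nyquist range [0, %g]",
                 lo, hi, ny))
  f <- spec$frequencies
  p <- spec$psd
  at <- function(q) stats::approx(f, p, xout = q, rule = 2)$y
  knots <- c(lo, f[f > lo & f < hi], hi)
  vals <- c(at(lo), p[f > lo & f < hi], at(hi))
  sum(diff(knots) * (head(vals, -1) + tail(vals, -1)) / 2)
}

#' Burg AR spectrum of a series, with AIC order selection
#'
#' Convenience wrapper: selects the order by [aicOrder()] (unless given),
#' fits [burgFit()], and returns the [arPSD()].
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param order AR order; `NULL` to select by AIC.
#' @param pMax AIC search bound; default `min(floor(N/4), 64)`.
#' @param nfft FFT length.
#' @return A `"SpectralEstimate"` with the fitted `"ARModel"` attached as
#'   attribute `"model"`.
#' @export
arSpectrum <- function(x, fs, order = NULL, pMax = NULL, nfft = 1024L) {
  x <- as.numeric(x)
  if (is.null(order)) {
    if (is.null(pMax)) pMax <- min(length(x) %/% 4L, 64L)
    order <- as.integer(aicOrder(x, pMax))
  }
  model <- burgFit(x, order)
  spec <- arPSD(model, fs = fs, nfft = nfft)
  attr(spec, "model") <- model
  spec
}
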