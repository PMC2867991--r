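#' Approximate entropy
#'
#' Regularity statistic of Pincus: the likelihood that runs of length `m`
#' that are similar (within tolerance `r` under the Chebyshev metric) remain
#' similar at length `m + 1`. For each template `X(i) = (x_i, ..., x_{i+m-1})`
#' the match fraction is
#' `C_i^m(r) = #(j : d[X(i), X(j)] <= r) / (N - m + 1)` (the template
#' matches itself, so `C_i > 0` always), `phi^m(r)` is the mean of
#' `ln C_i^m(r)`, and `ApEn(m, r, N) = phi^m(r) - phi^{m+1}(r)`. Larger
#' values indicate a greater rate of new-pattern generation, i.e. a more
#' complex series; a constant series gives exactly 0.
#'
#' `selfMatches = FALSE` selects the bias-corrected variant that excludes
#' the self-match while keeping the denominator `N - m`: its values differ
#' at order `1/N`, but sparse data can then leave a template with no match
#' at all, which raises an `r`-too-small error naming the offending
#' template (the statistic is undefined there). The default keeps the
#' always-defined standard form.
#'
#' The comparison is non-strict (`d <= r`) by default, matching Pincus's
#' definition; `strict = TRUE` uses `d < r` (the difference vanishes for
#' continuous-valued data).
#'
#' @param x numeric series of length `N >= m + 2`.
#' @param m pattern length (>= 1).
#' @param r tolerance, in the units of `x` (> 0).
#' @param strict use strict inequality `d < r`?
#' @param selfMatches include the self-match (standard definition)?
#' @return Non-negative scalar (up to numerical tolerance).
#' @examples
#' apen(sin(seq(0, 20, length.out = 300)), m = 2, r = 0.2)
#' @export
apen <- function(x, m, r, strict = FALSE, selfMatches = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  m <- as.integer(m)
  stopifnot(m >= 1L)
  if (n < m + 2L) stop(sprintf("series too short: N = %d < m + 2 = %d",
                               n, m + 2L))
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("tolerance r must be a single positive number")
  phi <- function(mm) {
    counts <- .apenCounts(x, mm, r, strict)
    ci <- if (selfMatches) (counts + 1) / (n - mm + 1L)
          else counts / (n - mm)
    if (any(ci == 0)) {
      idx <- which(ci == 0)[1L]
      stop(sprintf(
        "tolerance r = %g too small: template %d (length %d) has no match",
        r, idx, mm))
    }
    mean(log(ci))
  }
  phi(m) - phi(m + 1L)
}

#' Approximate entropy with SD-scaled tolerance
#'
#' Convenience wrapper setting `r = rFactor * sd(x)`, which makes the
#' statistic invariant under affine rescaling of the series. The default
#' `rFactor = 0.2` sits inside the conventional 0.1-0.25 band; 0.5 and 1.0
#' are common experiment presets.
#'
#' @inheritParams apen
#' @param rFactor tolerance as a multiple of the sample SD of `x`.
#' @return Non-negative scalar.
#' @export
apenScaled <- function(x, m = 2L, rFactor = 0.2, strict = FALSE,
                       selfMatches = TRUE) {
  s <- sd(x)
  if (is.na(s) || s == 0)
    stop("degenerate input: zero-variance series has no SD-scaled tolerance")
  apen(x, m, rFactor * s, strict = strict, selfMatches = selfMatches)
}
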