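#' @useDynLib chaosEEG, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats cor sd fft rnorm runif var lm coef quantile spec.pgram
#' @importFrom utils head tail
NULL

#' Recording: a multichannel sampled signal
#'
#' Container for a multichannel EEG-like recording: an ordered set of leads,
#' a common sampling rate, and a samples matrix with one row per lead.
#'
#' @slot leadLabels character vector of unique channel names, in order.
#' @slot fs sampling rate in Hz; the sampling interval is `1/fs` seconds.
#' @slot samples numeric matrix of amplitudes, one row per lead, `N` columns.
#' @slot meta free-text provenance string.
#'
#' @seealso [Recording()], [readRecordingCSV()], [syntheticRecording()]
#' @name Recording-class
#' @aliases Recording-class
#' @exportClass Recording
setClass("Recording",
  representation(
    leadLabels = "character",
    fs = "numeric",
    samples = "matrix",
    meta = "character"
  )
)

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive finite number")
  if (ncol(object@samples) < 2L)
    msg <- c(msg, "recording must have at least N = 2 samples per lead")
  if (nrow(object@samples) != length(object@leadLabels))
    msg <- c(msg, "samples must have one row per lead label")
  if (anyDuplicated(object@leadLabels))
    msg <- c(msg, "lead labels must be unique")
  if (length(object@leadLabels) == 0L)
    msg <- c(msg, "recording must have at least one lead")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "all samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param samples numeric matrix, one row per lead.
#' @param fs sampling rate in Hz.
#' @param leadLabels channel names; defaults to the matrix rownames.
#' @param meta free-text provenance.
#' @return A [Recording-class] object.
#' @examples
#' rec <- Recording(matrix(rnorm(20), nrow = 2,
#'                         dimnames = list(c("C3", "C4"), NULL)), fs = 250)
#' nSamples(rec)
#' @export
Recording <- function(samples, fs, leadLabels = rownames(samples),
                      meta = "") {
  samples <- as.matrix(samples)
  if (is.null(leadLabels))
    stop("leadLabels must be supplied when samples has no rownames")
  storage.mode(samples) <- "double"
  rownames(samples) <- leadLabels
  new("Recording", leadLabels = as.character(leadLabels), fs = fs,
      samples = samples, meta = meta)
}

#' EmbeddedTrajectory: an ordered set of phase-space points
#'
#' Result of delay-coordinate or multi-lead phase-space reconstruction.
#' For a delay embedding of a length-`N` series with dimension `m` and delay
#' `tau` (in samples), the trajectory has `M = N - (m-1)*tau` points; a
#' multi-lead embedding records `tau = 0` and keeps all `N` time points.
#'
#' @slot points numeric `M x m` matrix; rows ordered by time index.
#' @slot m embedding dimension.
#' @slot tau delay in samples (0 for multi-lead embeddings).
#' @slot sourceN length of the source series.
#' @seealso [delayEmbed()], [multileadEmbed()]
#' @name EmbeddedTrajectory-class
#' @exportClass EmbeddedTrajectory
setClass("EmbeddedTrajectory",
  representation(points = "matrix", m = "integer", tau = "integer",
                 sourceN = "integer")
)

setValidity("EmbeddedTrajectory", function(object) {
  msg <- character()
  M <- nrow(object@points)
  if (ncol(object@points) != object@m)
    msg <- c(msg, "points must have m columns")
  expected <- if (object@tau >= 1L)
    object@sourceN - (object@m - 1L) * object@tau else object@sourceN
  if (M != expected)
    msg <- c(msg, sprintf("point count %d != expected M = %d", M, expected))
  if (M < 1L) msg <- c(msg, "trajectory must contain at least one point")
  if (!all(is.finite(object@points)))
    msg <- c(msg, "all coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' SurrogateEnsemble: constrained randomisations of a series
#'
#' A set of IAAFT surrogates sharing the original series' amplitude
#' distribution and (approximately) its power spectrum; the linear-stochastic
#' null for the determinism test.
#'
#' @slot surrogates list of numeric series, all the same length.
#' @slot nIter IAAFT iterations used per surrogate.
#' @slot seed integer seed the ensemble was derived from.
#' @seealso [iaaftSurrogate()], [surrogateEnsemble()], [determinismRatio()]
#' @name SurrogateEnsemble-class
#' @exportClass SurrogateEnsemble
setClass("SurrogateEnsemble",
  representation(surrogates = "list", nIter = "integer", seed = "integer")
)

setValidity("SurrogateEnsemble", function(object) {
  msg <- character()
  if (length(object@surrogates) < 1L)
    msg <- c(msg, "ensemble must contain at least one surrogate")
  lens <- vapply(object@surrogates, length, integer(1))
  if (length(unique(lens)) > 1L)
    msg <- c(msg, "all surrogates must have the same length")
  if (length(msg)) msg else TRUE
})

#' SOMGrid: a trained two-dimensional self-organizing map
#'
#' Rectangular lattice of weight vectors trained by the classical SOM rule,
#' with optional per-node class labels and the feature normalisation constants
#' applied before training (reused at prediction time). Nodes are indexed
#' row-major: node `(r, c)` is row `(r-1)*cols + c` of `weights`.
#'
#' @slot rows,cols grid shape.
#' @slot weights numeric `(rows*cols) x d` matrix of node weight vectors.
#' @slot nodeLabels character vector of per-node class labels (length 0 until
#'   [labelNodes()] is applied).
#' @slot center,scale per-dimension normalisation applied to inputs.
#' @slot featureNames column names of the training features.
#' @slot trainingLog list: epochs, final learning rate, final radius.
#' @slot seed RNG seed used for initialisation and shuffling.
#' @seealso [trainSOM()], [labelNodes()], [predict,SOMGrid-method]
#' @name SOMGrid-class
#' @exportClass SOMGrid
setClass("SOMGrid",
  representation(rows = "integer", cols = "integer", weights = "matrix",
                 nodeLabels = "character", center = "numeric",
                 scale = "numeric", featureNames = "character",
                 trainingLog = "list", seed = "integer")
)

setValidity("SOMGrid", function(object) {
  msg <- character()
  if (nrow(object@weights) != object@rows * object@cols)
    msg <- c(msg, "weights must have rows*cols rows")
  if (!all(is.finite(object@weights)))
    msg <- c(msg, "weights must be finite")
  if (length(object@nodeLabels) &&
      length(object@nodeLabels) != nrow(object@weights))
    msg <- c(msg, "nodeLabels must be empty or one per node")
  if (length(msg)) msg else TRUE
})
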