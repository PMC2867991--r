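#' @describeIn Recording-class channel names, in order.
#' @param object,x a `Recording`.
#' @export
setGeneric("leadLabels", function(object) standardGeneric("leadLabels"))
setMethod("leadLabels", "Recording", function(object) object@leadLabels)

#' @describeIn Recording-class sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
setMethod("samplingRate", "Recording", function(object) object@fs)

#' @describeIn Recording-class the lead-by-time amplitude matrix.
#' @export
setGeneric("sampleMatrix", function(object) standardGeneric("sampleMatrix"))
setMethod("sampleMatrix", "Recording", function(object) object@samples)

#' @describeIn Recording-class number of samples per lead.
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
setMethod("nSamples", "Recording", function(object) ncol(object@samples))

#' @describeIn Recording-class number of leads.
#' @export
setGeneric("nLeads", function(object) standardGeneric("nLeads"))
setMethod("nLeads", "Recording", function(object) nrow(object@samples))

#' @describeIn Recording-class extract one lead as a numeric series.
#' @param lead a lead name.
#' @export
setGeneric("getLead", function(object, lead) standardGeneric("getLead"))
setMethod("getLead", "Recording", function(object, lead) {
  if (!lead %in% object@leadLabels)
    stop(sprintf("unknown lead '%s'", lead))
  as.numeric(object@samples[lead, ])
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d leads x %d samples @ %g Hz (%.2f s)\n",
              nLeads(object), nSamples(object), object@fs,
              nSamples(object) / object@fs))
  cat("  leads:", paste(object@leadLabels, collapse = ", "), "\n")
  if (nzchar(object@meta)) cat("  meta:", object@meta, "\n")
})

#' @describeIn EmbeddedTrajectory-class the `M x m` coordinate matrix.
#' @param object an `EmbeddedTrajectory`.
#' @export
setGeneric("trajectoryPoints",
           function(object) standardGeneric("trajectoryPoints"))
setMethod("trajectoryPoints", "EmbeddedTrajectory",
          function(object) object@points)

#' @describeIn EmbeddedTrajectory-class number of phase-space points `M`.
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))
setMethod("nPoints", "EmbeddedTrajectory", function(object) nrow(object@points))

#' @describeIn EmbeddedTrajectory-class embedding dimension `m`.
#' @export
setGeneric("embeddingDim", function(object) standardGeneric("embeddingDim"))
setMethod("embeddingDim", "EmbeddedTrajectory", function(object) object@m)

#' @describeIn EmbeddedTrajectory-class delay `tau` in samples.
#' @export
setGeneric("embeddingDelay",
           function(object) standardGeneric("embeddingDelay"))
setMethod("embeddingDelay", "EmbeddedTrajectory", function(object) object@tau)

setMethod("show", "EmbeddedTrajectory", function(object) {
  cat(sprintf(
    "EmbeddedTrajectory: %d points in %d dimensions (tau = %d, N = %d)\n",
    nPoints(object), object@m, object@tau, object@sourceN))
})

#' @describeIn SurrogateEnsemble-class the surrogate series, as a list.
#' @param object a `SurrogateEnsemble`.
#' @export
setGeneric("surrogates", function(object) standardGeneric("surrogates"))
setMethod("surrogates", "SurrogateEnsemble", function(object) object@surrogates)

setMethod("show", "SurrogateEnsemble", function(object) {
  cat(sprintf("SurrogateEnsemble: %d IAAFT surrogates of length %d (%d iterations, seed %d)\n",
              length(object@surrogates), length(object@surrogates[[1]]),
              object@nIter, object@seed))
})

#' @describeIn SOMGrid-class node weight matrix, row-major node order.
#' @param object a `SOMGrid`.
#' @export
setGeneric("somWeights", function(object) standardGeneric("somWeights"))
setMethod("somWeights", "SOMGrid", function(object) object@weights)

#' @describeIn SOMGrid-class per-node class labels (length 0 if unlabelled).
#' @export
setGeneric("nodeLabels", function(object) standardGeneric("nodeLabels"))
setMethod("nodeLabels", "SOMGrid", function(object) object@nodeLabels)

setMethod("show", "SOMGrid", function(object) {
  cat(sprintf("SOMGrid: %d x %d nodes, %d-dimensional weights%s\n",
              object@rows, object@cols, ncol(object@weights),
              if (length(object@nodeLabels)) ", labelled" else ""))
  if (length(object@trainingLog))
    cat(sprintf("  trained %d epochs (seed %d)\n",
                object@trainingLog$epochs, object@seed))
})
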