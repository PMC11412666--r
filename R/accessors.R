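#' Accessors for avTRF data objects
#'
#' Small accessor functions exposing slots of the package's S4 containers;
#' user code should use these rather than \code{@}.
#'
#' @param x,object an avTRF object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("sampleRate", "AudioSignal", function(x) x@rate)
#' @rdname accessors
#' @export
setMethod("sampleRate", "EEGRecording", function(x) x@rate)
#' @rdname accessors
#' @export
setMethod("sampleRate", "EEGEpoch", function(x) x@rate)
#' @rdname accessors
#' @export
setMethod("sampleRate", "FeatureStream", function(x) x@rate)

#' @rdname accessors
#' @export
samples <- function(x) x@samples

#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EEGEpoch", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "TRFModel", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EvalResult", function(x) x@channelLabels)

#' @rdname accessors
#' @export
setMethod("featureNames", "FeatureStream", function(x) x@featureNames)
#' @rdname accessors
#' @export
setMethod("featureNames", "TRFModel", function(x) x@featureNames)

#' @rdname accessors
#' @export
setMethod("modality", "FeatureStream", function(x) x@modality)

#' @rdname accessors
#' @export
setMethod("streamData", "FeatureStream", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("epochData", "EEGRecording", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("epochData", "EEGEpoch", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("condition", "EEGEpoch", function(x) x@condition)
#' @rdname accessors
#' @export
setMethod("condition", "TRFModel", function(x) x@condition)

#' @rdname accessors
#' @export
setMethod("subjectId", "EEGEpoch", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("trailerId", "EEGEpoch", function(x) x@trailerId)

#' @rdname accessors
#' @export
setMethod("tiers", "AnnotationTrack", function(x) x@tiers)

#' @rdname accessors
#' @export
setMethod("nFilters", "GaborBank", function(x) nrow(x@filters))
#' @rdname accessors
#' @export
setMethod("filterTable", "GaborBank", function(x) x@filters)

#' @rdname accessors
#' @export
setMethod("weights", "TRFModel", function(object, ...) object@weights)

#' @rdname accessors
#' @export
setMethod("lagTimes", "TRFModel", function(x) x@lags / x@rate)

#' @rdname accessors
#' @export
setMethod("lambdaValues", "TRFModel", function(x) x@lambda)

#' @rdname accessors
#' @export
setMethod("rValues", "EvalResult", function(x) x@r)
#' @rdname accessors
#' @export
setMethod("pValues", "EvalResult", function(x) x@p)

#' Express TRF weights on the native feature/response scale
#'
#' When a model is fit on column-standardized features and responses, the
#' stored weights live in z-scored space. This rescales them to the original
#' units (weight for feature f, channel n multiplied by sd(y_n)/sd(s_f)),
#' which is the scale on which fitted kernels are comparable to generative
#' ground-truth kernels.
#'
#' @param model a \linkS4class{TRFModel}.
#' @return features x lags x channels array.
#' @export
setMethod("nativeWeights", "TRFModel", function(model) {
  w <- model@weights
  if (length(model@featureScale) == 0L) return(w)
  nF <- dim(w)[1]; nL <- dim(w)[2]
  # featureScale is per embedded column (feature-major, lag-minor)
  sxMat <- t(matrix(model@featureScale, nL, nF))   # features x lags
  sy <- model@responseScale
  w <- sweep(w, c(1, 2), sxMat, "/")
  sweep(w, 3L, sy, "*")
})

setMethod("show", "AnnotationTrack", function(object) {
  cat("AnnotationTrack with", length(object@tiers), "tier(s)\n")
  for (nm in names(object@tiers))
    cat(sprintf("  %-12s %4d interval(s)\n", nm, nrow(object@tiers[[nm]])))
})

setMethod("show", "AudioSignal", function(object) {
  cat(sprintf("AudioSignal: %d samples at %g Hz (%.2f s)\n",
              length(object@samples), object@rate,
              length(object@samples) / object@rate))
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples at %g Hz%s\n",
              nrow(object@data), ncol(object@data), object@rate,
              if (length(object@auxAudio)) " (+aux audio)" else ""))
})

setMethod("show", "EEGEpoch", function(object) {
  cat(sprintf("EEGEpoch [%s] subject %s, trailer %s: %d ch x %d samples (128 Hz)\n",
              object@condition, object@subjectId, object@trailerId,
              nrow(object@data), ncol(object@data)))
})

setMethod("show", "FeatureStream", function(object) {
  cat(sprintf("FeatureStream: %d samples x %d features at %g Hz (%d auditory, %d visual)\n",
              nrow(object@data), ncol(object@data), object@rate,
              sum(object@modality == "auditory"),
              sum(object@modality == "visual")))
})

setMethod("show", "GaborBank", function(object) {
  cat(sprintf("GaborBank: %d quadrature-pair filters (%d x %d px frames)\n",
              nrow(object@filters), object@params$imageSize,
              object@params$imageSize))
})

setMethod("show", "TRFModel", function(object) {
  d <- dim(object@weights)
  cat(sprintf("TRFModel [%s]: %d features x %d lags x %d channels\n",
              object@condition, d[1], d[2], d[3]))
  cat(sprintf("  lags 0-%.1f ms; lambda in [%.3g, %.3g]; trained on: %s\n",
              1000 * max(object@lags) / object@rate,
              min(object@lambda), max(object@lambda),
              paste(object@trainTrailers, collapse = ", ")))
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult '%s': %d channels, r in [%.3f, %.3f]",
              object@modelTag, length(object@r),
              min(object@r), max(object@r)))
  if (!all(is.na(object@p)))
    cat(sprintf(", %d channel(s) with p < 0.05", sum(object@p < 0.05, na.rm = TRUE)))
  cat("\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d features x %d lags x %d channels, SNR %g dB, seed %d\n",
              dim(object@kernels)[1], dim(object@kernels)[2],
              dim(object@kernels)[3], object@snrDb[1], object@seed))
})

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf("SimulatedDataset: %d trailer(s) x %d condition(s); test trailers: %s\n",
              length(object@features), length(object@eeg[[1]]),
              paste(object@testTrailers, collapse = ", ")))
})
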