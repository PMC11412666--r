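#' @import methods
NULL

# Conditions recognised throughout the package.
.CONDITIONS <- c("AV", "A", "V")

#' AnnotationTrack: time-aligned interval annotations
#'
#' A set of named tiers, each a data.frame of half-open intervals
#' \code{[start, end)} in seconds with a character label. Point annotations
#' (e.g. scene cuts) are stored as zero-length intervals (\code{start == end}).
#'
#' @slot tiers named list of data.frames with columns \code{start},
#'   \code{end}, \code{label}.
#' @export
setClass("AnnotationTrack", representation(tiers = "list"))

setValidity("AnnotationTrack", function(object) {
  tl <- object@tiers
  if (length(tl) && is.null(names(tl))) return("tiers must be named")
  for (nm in names(tl)) {
    tier <- tl[[nm]]
    if (!is.data.frame(tier) ||
        !all(c("start", "end", "label") %in% names(tier)))
      return(sprintf("tier '%s' must have columns start, end, label", nm))
    if (nrow(tier) == 0L) next
    if (any(!is.finite(tier$start)) || any(!is.finite(tier$end)))
      return(sprintf("tier '%s' has non-finite times", nm))
    if (any(tier$start < 0) || any(tier$end < tier$start))
      return(sprintf("tier '%s' violates 0 <= start <= end", nm))
    if (is.unsorted(tier$start))
      return(sprintf("tier '%s' intervals are not sorted by start", nm))
    if (nrow(tier) > 1L) {
      # overlap check on true intervals (zero-length points may coincide)
      s <- tier$start; e <- tier$end
      if (any(s[-1L] < e[-nrow(tier)] - 1e-9))
        return(sprintf("tier '%s' has overlapping intervals", nm))
    }
  }
  TRUE
})

#' Construct an AnnotationTrack
#'
#' @param tiers named list of data.frames (columns start, end, label).
#' @return an \linkS4class{AnnotationTrack}.
#' @export
AnnotationTrack <- function(tiers = list()) {
  tiers <- lapply(tiers, function(t) {
    t <- as.data.frame(t)[, c("start", "end", "label")]
    t$label <- as.character(t$label)
    t[order(t$start), , drop = FALSE]
  })
  new("AnnotationTrack", tiers = tiers)
}

#' AudioSignal: a mono waveform
#'
#' @slot samples numeric vector in [-1, 1].
#' @slot rate sampling rate in samples/s.
#' @export
setClass("AudioSignal",
         representation(samples = "numeric", rate = "numeric"))

setValidity("AudioSignal", function(object) {
  if (length(object@rate) != 1L || object@rate <= 0)
    return("rate must be a positive scalar")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    return("samples must be finite")
  TRUE
})

#' @rdname AudioSignal-class
#' @param samples,rate see slots.
#' @export
AudioSignal <- function(samples, rate) {
  new("AudioSignal", samples = as.numeric(samples), rate = as.numeric(rate))
}

#' EEGRecording: a raw multi-channel recording
#'
#' @slot data channels x samples matrix.
#' @slot rate sampling rate (samples/s).
#' @slot channelLabels one 10-20 montage label per row.
#' @slot auxAudio optionally, the stimulus audio recorded alongside the EEG
#'   (used for alignment), at the same rate unless \code{auxRate} is set.
#' @slot auxRate sampling rate of \code{auxAudio}.
#' @export
setClass("EEGRecording",
         representation(data = "matrix", rate = "numeric",
                        channelLabels = "character", auxAudio = "numeric",
                        auxRate = "numeric"))

setValidity("EEGRecording", function(object) {
  if (nrow(object@data) != length(object@channelLabels))
    return("row count must equal channel label count")
  if (anyDuplicated(object@channelLabels))
    return("channel labels must be unique")
  if (length(object@rate) != 1L || object@rate <= 0)
    return("rate must be a positive scalar")
  TRUE
})

#' @rdname EEGRecording-class
#' @param data,rate,channelLabels,auxAudio,auxRate see slots.
#' @export
EEGRecording <- function(data, rate, channelLabels,
                         auxAudio = numeric(0), auxRate = rate) {
  data <- as.matrix(data)
  if (nrow(data) == length(channelLabels)) rownames(data) <- channelLabels
  new("EEGRecording", data = data, rate = as.numeric(rate),
      channelLabels = as.character(channelLabels),
      auxAudio = as.numeric(auxAudio), auxRate = as.numeric(auxRate))
}

#' EEGEpoch: a condition-tagged, stimulus-aligned EEG segment at 128 Hz
#'
#' @slot data channels x samples matrix.
#' @slot rate sampling rate; always 128.
#' @slot channelLabels channel labels.
#' @slot condition one of "AV", "A", "V".
#' @slot subjectId,trailerId provenance tags.
#' @export
setClass("EEGEpoch",
         representation(data = "matrix", rate = "numeric",
                        channelLabels = "character", condition = "character",
                        subjectId = "character", trailerId = "character"))

setValidity("EEGEpoch", function(object) {
  if (nrow(object@data) != length(object@channelLabels))
    return("row count must equal channel label count")
  if (!identical(object@rate, 128))
    return("EEGEpoch rate must be exactly 128")
  if (!object@condition %in% .CONDITIONS)
    return("condition must be one of AV, A, V")
  TRUE
})

#' @rdname EEGEpoch-class
#' @param data,channelLabels,condition,subjectId,trailerId see slots.
#' @export
EEGEpoch <- function(data, channelLabels, condition,
                     subjectId = "S01", trailerId = "tr01") {
  data <- as.matrix(data)
  if (nrow(data) == length(channelLabels)) rownames(data) <- channelLabels
  new("EEGEpoch", data = data, rate = 128,
      channelLabels = as.character(channelLabels),
      condition = condition, subjectId = subjectId, trailerId = trailerId)
}

#' FeatureStream: a (time x features) stimulus representation at 128 Hz
#'
#' @slot data time x features matrix.
#' @slot featureNames one name per column.
#' @slot modality per-feature tag, "auditory" or "visual".
#' @slot rate sampling rate (128).
#' @export
setClass("FeatureStream",
         representation(data = "matrix", featureNames = "character",
                        modality = "character", rate = "numeric"))

setValidity("FeatureStream", function(object) {
  if (ncol(object@data) != length(object@featureNames))
    return("column count must equal feature name count")
  if (length(object@modality) != length(object@featureNames))
    return("modality must be tagged per feature")
  if (!all(object@modality %in% c("auditory", "visual")))
    return("modality tags must be 'auditory' or 'visual'")
  if (anyNA(object@data)) return("feature data must contain no NAs")
  TRUE
})

#' @rdname FeatureStream-class
#' @param data,featureNames,modality,rate see slots.
#' @export
FeatureStream <- function(data, featureNames, modality, rate = 128) {
  data <- as.matrix(data)
  if (length(modality) == 1L) modality <- rep(modality, ncol(data))
  colnames(data) <- featureNames
  new("FeatureStream", data = data, featureNames = as.character(featureNames),
      modality = modality, rate = as.numeric(rate))
}

#' GaborBank: a spatiotemporal motion-energy filter bank specification
#'
#' One row per quadrature pair: spatial frequency (cycles/image), temporal
#' frequency (Hz), direction (degrees), center (image fractions), spatial and
#' temporal envelope SDs. Both 0 and 90 degree phases of each pair are
#' realised when the bank is applied.
#'
#' @slot filters data.frame of filter specifications.
#' @slot params list of the construction parameters.
#' @export
setClass("GaborBank", representation(filters = "data.frame", params = "list"))

#' TRFModel: fitted delay-embedded ridge encoding model
#'
#' @slot weights features x lags x channels array (standardized space when
#'   \code{standardize} was used; see \code{\link{nativeWeights}}).
#' @slot lambda per-channel ridge parameter.
#' @slot lags integer sample lags (non-negative, unit step).
#' @slot rate sampling rate the lags refer to (128).
#' @slot featureNames,channelLabels axis names.
#' @slot trainTrailers,condition training provenance.
#' @slot featureCenter,featureScale,responseCenter,responseScale
#'   standardization statistics from the training set (empty when
#'   standardization was disabled).
#' @export
setClass("TRFModel",
         representation(weights = "array", lambda = "numeric",
                        lags = "integer", rate = "numeric",
                        featureNames = "character", channelLabels = "character",
                        trainTrailers = "character", condition = "character",
                        featureCenter = "numeric", featureScale = "numeric",
                        responseCenter = "numeric", responseScale = "numeric"))

setValidity("TRFModel", function(object) {
  d <- dim(object@weights)
  if (length(d) != 3L) return("weights must be features x lags x channels")
  if (d[1L] != length(object@featureNames)) return("feature axis mismatch")
  if (d[2L] != length(object@lags)) return("lag axis mismatch")
  if (d[3L] != length(object@channelLabels)) return("channel axis mismatch")
  if (any(!is.finite(object@weights))) return("weights must be finite")
  if (any(object@lags < 0L) || is.unsorted(object@lags, strictly = TRUE))
    return("lags must be non-negative and strictly increasing")
  TRUE
})

#' EvalResult: per-channel model evaluation
#'
#' @slot r per-channel Pearson correlation between predicted and actual EEG.
#' @slot p per-channel permutation p-value (NA when no shuffle test was run).
#' @slot nTestSamples test-set length in samples.
#' @slot modelTag free-form model identifier.
#' @slot channelLabels channel labels.
#' @export
setClass("EvalResult",
         representation(r = "numeric", p = "numeric", nTestSamples = "integer",
                        modelTag = "character", channelLabels = "character"))

setValidity("EvalResult", function(object) {
  if (any(abs(object@r) > 1 + 1e-12, na.rm = TRUE)) return("|r| must be <= 1")
  pp <- object@p[!is.na(object@p)]
  if (length(pp) && (any(pp < 0) || any(pp > 1))) return("p must be in [0,1]")
  TRUE
})

#' GroundTruth: the simulator's known generative parameters
#'
#' @slot kernels true weight tensor (features x lags x channels), with the
#'   topographic modality gains already applied.
#' @slot auditoryGain,visualGain per-channel gains.
#' @slot snrDb per-channel SNR of the audiovisual response, in dB.
#' @slot seed integer seed the dataset was generated from.
#' @slot phonemeRate,cutRate event rates (events/s).
#' @slot lags,featureNames,channelLabels,modality axis metadata.
#' @export
setClass("GroundTruth",
         representation(kernels = "array", auditoryGain = "numeric",
                        visualGain = "numeric", snrDb = "numeric",
                        seed = "integer", phonemeRate = "numeric",
                        cutRate = "numeric", lags = "integer",
                        featureNames = "character", channelLabels = "character",
                        modality = "character"))

#' SimulatedDataset: features + three-condition EEG for several trailers
#'
#' @slot features named list (by trailer) of \linkS4class{FeatureStream}s;
#'   identical across conditions of the same trailer.
#' @slot eeg nested named list: \code{eeg[[trailer]][[condition]]} is an
#'   \linkS4class{EEGEpoch}.
#' @slot truth the \linkS4class{GroundTruth}.
#' @slot testTrailers trailer ids designated as the held-out test set.
#' @export
setClass("SimulatedDataset",
         representation(features = "list", eeg = "list",
                        truth = "GroundTruth", testTrailers = "character"))
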