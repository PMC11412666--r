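#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("streamData", function(x) standardGeneric("streamData"))

#' @rdname accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("trailerId", function(x) standardGeneric("trailerId"))

#' @rdname accessors
#' @export
setGeneric("tiers", function(x) standardGeneric("tiers"))

#' @rdname accessors
#' @export
setGeneric("nFilters", function(x) standardGeneric("nFilters"))

#' @rdname accessors
#' @export
setGeneric("filterTable", function(x) standardGeneric("filterTable"))

#' @rdname accessors
#' @export
setGeneric("weights", function(object, ...) standardGeneric("weights"))

#' @rdname accessors
#' @export
setGeneric("lagTimes", function(x) standardGeneric("lagTimes"))

#' @rdname accessors
#' @export
setGeneric("lambdaValues", function(x) standardGeneric("lambdaValues"))

#' @rdname accessors
#' @export
setGeneric("rValues", function(x) standardGeneric("rValues"))

#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname nativeWeights
#' @export
setGeneric("nativeWeights", function(model) standardGeneric("nativeWeights"))
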