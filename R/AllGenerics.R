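#' @rdname EpochSet-accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("epochInfo", function(x) standardGeneric("epochInfo"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname SubjectSession-accessors
#' @export
setGeneric("trialLog", function(x) standardGeneric("trialLog"))

#' @rdname SubjectSession-accessors
#' @export
setGeneric("agentSpecOf", function(x) standardGeneric("agentSpecOf"))

#' @rdname Montage-accessors
#' @export
setGeneric("roiChannels", function(x, roi) standardGeneric("roiChannels"))

#' @rdname Montage-accessors
#' @export
setGeneric("outerRing", function(x) standardGeneric("outerRing"))

#' @rdname Montage-accessors
#' @export
setGeneric("mastoids", function(x) standardGeneric("mastoids"))

#' @rdname Montage-accessors
#' @export
setGeneric("channelPositions", function(x) standardGeneric("channelPositions"))
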