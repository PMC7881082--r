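#' @rdname EEGRecord-class
#' @param object,x an object.
#' @export
setGeneric("eegSignal", function(x) standardGeneric("eegSignal"))

#' @rdname EEGRecord-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EEGRecord-class
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname EEGRecord-class
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname EEGRecord-class
#' @export
setGeneric("recordId", function(x) standardGeneric("recordId"))

#' @rdname EEGRecord-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname EEGRecord-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname EEGRecord-class
#' @export
setGeneric("recordDuration", function(x) standardGeneric("recordDuration"))

#' @rdname EEGWindow-class
#' @param x an object.
#' @export
setGeneric("windowLabel", function(x) standardGeneric("windowLabel"))

#' @rdname EEGWindow-class
#' @export
setGeneric("windowStart", function(x) standardGeneric("windowStart"))

#' @rdname FeatureTable-class
#' @param x an object.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname FeatureTable-class
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname FeatureTable-class
#' @export
setGeneric("windowInfo", function(x) standardGeneric("windowInfo"))

#' @rdname ChannelRanking-class
#' @param x an object.
#' @export
setGeneric("selectedChannels", function(x) standardGeneric("selectedChannels"))

#' @rdname ChannelRanking-class
#' @export
setGeneric("channelVariances", function(x) standardGeneric("channelVariances"))

#' @rdname MetricsReport-class
#' @param x an object.
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @rdname ConfusionCounts-class
#' @param x an object.
#' @export
setGeneric("countValues", function(x) standardGeneric("countValues"))
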