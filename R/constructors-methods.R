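#' Construct an EEG record
#'
#' @param signal numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate, Hz.
#' @param channelLabels channel names; defaults to \code{CH1..CHn}.
#' @param annotations data.frame with columns \code{start_s}, \code{end_s}
#'   (seconds, half-open intervals), or NULL for none.
#' @param recordId record identifier string.
#' @return an [EEGRecord-class].
#' @examples
#' rec <- eegRecord(matrix(rnorm(2 * 100), 2), fs = 10)
#' nChannels(rec)
#' recordDuration(rec)
#' @export
eegRecord <- function(signal, fs, channelLabels = NULL, annotations = NULL,
                      recordId = "record") {
    signal <- as.matrix(signal)
    storage.mode(signal) <- "double"
    if (is.null(channelLabels))
        channelLabels <- paste0("CH", seq_len(nrow(signal)))
    if (is.null(annotations))
        annotations <- data.frame(start_s = numeric(), end_s = numeric())
    annotations <- as.data.frame(annotations)[, c("start_s", "end_s")]
    new("EEGRecord", signal = signal, fs = as.numeric(fs),
        channelLabels = as.character(channelLabels),
        annotations = annotations, recordId = as.character(recordId))
}

#' Construct a feature table
#'
#' Lower-level constructor used by [buildFeatureTable()],
#' [simulateFeatureTable()] and [readFeatureTable()].
#'
#' @param features data.frame (or matrix) with the eleven feature columns
#'   in canonical order (\code{STD, Mean, Max, Min, Var, Med, SKW, ENT, KRT,
#'   MOM, POW}).
#' @param state character vector of \code{"seizure"}/\code{"normal"} labels.
#' @param windowInfo optional data.frame with \code{record_id},
#'   \code{start_s} per row.
#' @return a [FeatureTable-class].
#' @export
featureTable <- function(features, state, windowInfo = NULL) {
    features <- as.data.frame(features)
    if (is.null(windowInfo))
        windowInfo <- data.frame(record_id = rep(NA_character_, nrow(features)),
                                 start_s = rep(NA_real_, nrow(features)))
    new("FeatureTable", features = features, state = as.character(state),
        windowInfo = as.data.frame(windowInfo))
}

#' Construct confusion counts directly
#'
#' @param tp,tn,fp,fn nonnegative integer counts (seizure = positive class).
#' @return a [ConfusionCounts-class].
#' @examples
#' computeMetrics(confusionCountsFromValues(37, 31, 6, 6))
#' @export
confusionCountsFromValues <- function(tp, tn, fp, fn) {
    new("ConfusionCounts", tp = as.integer(tp), tn = as.integer(tn),
        fp = as.integer(fp), fn = as.integer(fn))
}

## ---- accessors ------------------------------------------------------------

#' @rdname EEGRecord-class
#' @export
setMethod("eegSignal", "EEGRecord", function(x) x@signal)
#' @rdname EEGRecord-class
#' @export
setMethod("samplingRate", "EEGRecord", function(x) x@fs)
#' @rdname EEGRecord-class
#' @export
setMethod("channelLabels", "EEGRecord", function(x) x@channelLabels)
#' @rdname EEGRecord-class
#' @export
setMethod("annotations", "EEGRecord", function(x) x@annotations)
#' @rdname EEGRecord-class
#' @export
setMethod("recordId", "EEGRecord", function(x) x@recordId)
#' @rdname EEGRecord-class
#' @export
setMethod("nChannels", "EEGRecord", function(x) nrow(x@signal))
#' @rdname EEGRecord-class
#' @export
setMethod("nSamples", "EEGRecord", function(x) ncol(x@signal))
#' @rdname EEGRecord-class
#' @export
setMethod("recordDuration", "EEGRecord", function(x) ncol(x@signal) / x@fs)

#' @rdname EEGWindow-class
#' @export
setMethod("eegSignal", "EEGWindow", function(x) x@signal)
#' @rdname EEGWindow-class
#' @export
setMethod("samplingRate", "EEGWindow", function(x) x@fs)
#' @rdname EEGWindow-class
#' @export
setMethod("windowLabel", "EEGWindow", function(x) x@label)
#' @rdname EEGWindow-class
#' @export
setMethod("windowStart", "EEGWindow", function(x) x@startS)
#' @rdname EEGWindow-class
#' @export
setMethod("recordId", "EEGWindow", function(x) x@recordId)
#' @rdname EEGWindow-class
#' @export
setMethod("nChannels", "EEGWindow", function(x) nrow(x@signal))
#' @rdname EEGWindow-class
#' @export
setMethod("nSamples", "EEGWindow", function(x) ncol(x@signal))

#' @rdname FeatureTable-class
#' @export
setMethod("featureMatrix", "FeatureTable",
          function(x) as.matrix(x@features))
#' @rdname FeatureTable-class
#' @export
setMethod("stateLabels", "FeatureTable", function(x) x@state)
#' @rdname FeatureTable-class
#' @export
setMethod("windowInfo", "FeatureTable", function(x) x@windowInfo)
#' @rdname FeatureTable-class
#' @export
setMethod("nrow", "FeatureTable", function(x) base::nrow(x@features))

#' Subset the rows of a feature table
#' @param x a [FeatureTable-class].
#' @param i row index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
    new("FeatureTable", features = x@features[i, , drop = FALSE],
        state = x@state[i], windowInfo = x@windowInfo[i, , drop = FALSE])
})

#' @rdname ChannelRanking-class
#' @export
setMethod("selectedChannels", "ChannelRanking", function(x) x@selected)
#' @rdname ChannelRanking-class
#' @export
setMethod("channelVariances", "ChannelRanking", function(x) x@variances)

#' @rdname MetricsReport-class
#' @export
setMethod("metricValues", "MetricsReport", function(x) x@metrics)

#' @rdname ConfusionCounts-class
#' @export
setMethod("countValues", "ConfusionCounts", function(x)
    c(tp = x@tp, tn = x@tn, fp = x@fp, fn = x@fn))

## ---- show methods ---------------------------------------------------------

setMethod("show", "EEGRecord", function(object) {
    cat(sprintf("EEGRecord '%s': %d channels x %d samples @ %g Hz (%.1f s)\n",
                object@recordId, nrow(object@signal), ncol(object@signal),
                object@fs, ncol(object@signal) / object@fs))
    if (nrow(object@annotations))
        cat(sprintf("  %d seizure annotation(s): %s\n",
                    nrow(object@annotations),
                    paste(sprintf("[%g, %g)", object@annotations$start_s,
                                  object@annotations$end_s), collapse = " ")))
    else cat("  no seizure annotations\n")
})

setMethod("show", "EEGWindow", function(object) {
    cat(sprintf("EEGWindow [%s] record '%s' @ %g s: %d channels x %d samples @ %g Hz\n",
                object@label, object@recordId, object@startS,
                nrow(object@signal), ncol(object@signal), object@fs))
})

setMethod("show", "FeatureTable", function(object) {
    tab <- table(factor(object@state, levels = .LABEL_LEVELS))
    cat(sprintf("FeatureTable: %d epochs (%d seizure, %d normal), %d features\n",
                base::nrow(object@features), tab[["seizure"]], tab[["normal"]],
                ncol(object@features)))
    if (base::nrow(object@features)) {
        print(utils::head(cbind(object@features,
                                State = object@state), 4L))
        if (base::nrow(object@features) > 4L) cat("  ...\n")
    }
})

setMethod("show", "ChannelRanking", function(object) {
    cat(sprintf("ChannelRanking: top %d of %d channels by variance\n",
                object@k, length(object@variances)))
    cat("  selected (descending variance):",
        paste(sprintf("CH%d (%.4g)", object@selected,
                      object@variances[object@selected]), collapse = ", "), "\n")
})

setMethod("show", "ConfusionCounts", function(object) {
    cat(sprintf("ConfusionCounts: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
                object@tp, object@tn, object@fp, object@fn,
                object@tp + object@tn + object@fp + object@fn))
})

setMethod("show", "MetricsReport", function(object) {
    show(object@counts)
    m <- object@metrics
    for (nm in names(m))
        cat(sprintf("  %-22s %s\n", nm,
                    ifelse(is.na(m[[nm]]), "undefined",
                           sprintf("%.5f", m[[nm]]))))
})

setMethod("show", "SeizureClassifier", function(object) {
    hp <- if (length(object@hyperparameters))
        paste(names(object@hyperparameters),
              vapply(object@hyperparameters, function(v)
                  paste(format(v), collapse = ","), character(1L)),
              sep = "=", collapse = ", ") else "defaults"
    cat(sprintf("SeizureClassifier '%s' (seed %d): %s\n",
                object@name, object@seed, hp))
})

setMethod("show", "SynthConfig", function(object) {
    cat(sprintf(
        "SynthConfig: %d channels @ %g Hz, %g s, %d seizure interval(s)\n",
        object@nChannels, object@fs, object@durationS,
        nrow(object@seizureIntervals)))
    cat(sprintf(
        "  burst channels {%s}, amplitude factor %g, background SD %g uV, spike %g Hz, seed %d\n",
        paste(object@burstChannels, collapse = ","), object@amplitudeFactor,
        object@backgroundSd, object@spikeFreqHz, object@seed))
})

#' Convert a metrics report to a one-row data.frame
#' @param x a [MetricsReport-class].
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "MetricsReport", function(x, ...) {
    cbind(as.data.frame(as.list(countValues(x@counts))),
          as.data.frame(as.list(x@metrics)))
})
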