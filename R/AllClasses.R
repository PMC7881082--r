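#' @import methods
NULL

## Canonical feature column order used everywhere (tables, CSV, classifiers).
.FEATURE_NAMES <- c("STD", "Mean", "Max", "Min", "Var", "Med",
                    "SKW", "ENT", "KRT", "MOM", "POW")

.LABEL_LEVELS <- c("seizure", "normal")

#' Multichannel EEG record
#'
#' An \code{EEGRecord} holds one continuous multichannel scalp EEG recording
#' in channel-major form (one row per electrode, one column per time sample,
#' microvolts), together with its sampling rate, channel labels, a record
#' identifier, and seizure annotations as half-open \code{[start_s, end_s)}
#' intervals in seconds from record start.
#'
#' @slot signal numeric matrix, channels x samples, microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector of unique channel names.
#' @slot annotations data.frame with numeric columns \code{start_s} and
#'   \code{end_s}; may have zero rows.
#' @slot recordId single string identifying the record.
#'
#' @seealso [eegRecord()] for the user-facing constructor, [readEDF()],
#'   [readCSVRecord()], [windowContinuous()], [windowRandom()].
#' @export
setClass("EEGRecord",
    slots = c(
        signal = "matrix",
        fs = "numeric",
        channelLabels = "character",
        annotations = "data.frame",
        recordId = "character"
    )
)

setValidity("EEGRecord", function(object) {
    msg <- character()
    if (!is.numeric(object@signal))
        msg <- c(msg, "signal must be a numeric matrix")
    if (nrow(object@signal) < 1L)
        msg <- c(msg, "record must have at least one channel")
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
        msg <- c(msg, "fs must be a single positive number")
    if (length(object@channelLabels) != nrow(object@signal))
        msg <- c(msg, "one channel label per signal row is required")
    if (anyDuplicated(object@channelLabels))
        msg <- c(msg, "channel labels must be unique")
    if (length(object@recordId) != 1L)
        msg <- c(msg, "recordId must be a single string")
    ann <- object@annotations
    if (!all(c("start_s", "end_s") %in% names(ann))) {
        msg <- c(msg, "annotations need columns start_s and end_s")
    } else if (nrow(ann) > 0L) {
        dur <- ncol(object@signal) / object@fs
        if (any(ann$start_s < 0) || any(ann$end_s <= ann$start_s))
            msg <- c(msg, "annotations must satisfy 0 <= start_s < end_s")
        if (any(ann$end_s > dur + 1e-9))
            msg <- c(msg, "annotations must lie within the record duration")
    }
    if (length(msg)) msg else TRUE
})

#' One labelled fixed-length EEG epoch
#'
#' An \code{EEGWindow} is a single multichannel epoch cut from an
#' [EEGRecord-class], the unit of classification. Its label is
#' \code{"seizure"} when the epoch lies entirely inside an annotated seizure
#' interval and \code{"normal"} when it lies entirely outside all of them;
#' straddling epochs are never constructed.
#'
#' @slot signal numeric matrix, channels x samples, microvolts.
#' @slot label \code{"seizure"} or \code{"normal"}.
#' @slot recordId id of the source record.
#' @slot startS epoch start in seconds from record start.
#' @slot fs sampling rate in Hz.
#'
#' @seealso [windowContinuous()], [windowRandom()], [channelVariance()].
#' @export
setClass("EEGWindow",
    slots = c(
        signal = "matrix",
        label = "character",
        recordId = "character",
        startS = "numeric",
        fs = "numeric"
    )
)

setValidity("EEGWindow", function(object) {
    msg <- character()
    if (!is.numeric(object@signal) || nrow(object@signal) < 1L)
        msg <- c(msg, "signal must be a numeric matrix with >= 1 channel")
    if (length(object@label) != 1L || !(object@label %in% .LABEL_LEVELS))
        msg <- c(msg, "label must be 'seizure' or 'normal'")
    if (length(object@fs) != 1L || object@fs <= 0)
        msg <- c(msg, "fs must be a single positive number")
    if (length(object@startS) != 1L || object@startS < 0)
        msg <- c(msg, "startS must be a single nonnegative number")
    if (length(msg)) msg else TRUE
})

#' Per-epoch channel ranking by amplitude variance
#'
#' Result of ranking the channels of one epoch by their amplitude variance
#' and keeping the top \code{k}. Selected indices are ordered by descending
#' variance, ties broken toward the lower channel index.
#'
#' @slot variances numeric vector of per-channel population variances
#'   (microvolts^2).
#' @slot selected integer vector of selected channel indices, descending
#'   variance order.
#' @slot k number of channels requested.
#'
#' @seealso [selectTopK()], [channelVariance()].
#' @export
setClass("ChannelRanking",
    slots = c(variances = "numeric", selected = "integer", k = "integer")
)

setValidity("ChannelRanking", function(object) {
    msg <- character()
    if (any(object@variances < 0, na.rm = TRUE))
        msg <- c(msg, "variances must be nonnegative")
    if (length(object@selected) != min(object@k, length(object@variances)))
        msg <- c(msg, "length(selected) must equal min(k, n_channels)")
    if (anyDuplicated(object@selected))
        msg <- c(msg, "selected indices must be unique")
    if (length(object@selected) && length(object@variances)) {
        unsel <- setdiff(seq_along(object@variances), object@selected)
        if (length(unsel) &&
            min(object@variances[object@selected]) <
                max(object@variances[unsel]) - 1e-12)
            msg <- c(msg, "every selected variance must be >= every unselected variance")
    }
    if (length(msg)) msg else TRUE
})

#' Feature table: one averaged 11-feature row per epoch
#'
#' A \code{FeatureTable} is the classifier-facing container: one row per
#' epoch with the eleven features (columns \code{STD, Mean, Max, Min, Var,
#' Med, SKW, ENT, KRT, MOM, POW}), the binary state label, and per-epoch
#' provenance (source record id and epoch start time).
#'
#' @slot features data.frame with exactly the eleven numeric feature columns.
#' @slot state character vector, \code{"seizure"}/\code{"normal"}, one per row.
#' @slot windowInfo data.frame with columns \code{record_id} and
#'   \code{start_s}, one row per feature row.
#'
#' @seealso [buildFeatureTable()], [featureTable()], [writeFeatureTable()],
#'   [trainClassifier()], [crossValidate()].
#' @export
setClass("FeatureTable",
    slots = c(
        features = "data.frame",
        state = "character",
        windowInfo = "data.frame"
    )
)

setValidity("FeatureTable", function(object) {
    msg <- character()
    if (!identical(names(object@features), .FEATURE_NAMES))
        msg <- c(msg, sprintf("feature columns must be exactly: %s",
                              paste(.FEATURE_NAMES, collapse = ", ")))
    if (!all(vapply(object@features, is.numeric, logical(1L))))
        msg <- c(msg, "all feature columns must be numeric")
    if (length(object@state) != nrow(object@features))
        msg <- c(msg, "one state label per feature row is required")
    if (!all(object@state %in% .LABEL_LEVELS))
        msg <- c(msg, "state labels must be 'seizure' or 'normal'")
    if (nrow(object@windowInfo) != nrow(object@features))
        msg <- c(msg, "windowInfo must have one row per feature row")
    if (length(msg)) msg else TRUE
})

#' Confusion counts of one binary evaluation
#'
#' True/false positive/negative counts with \emph{seizure as the positive
#' class}. Feeds [computeMetrics()].
#'
#' @slot tp,tn,fp,fn nonnegative integer counts.
#' @export
setClass("ConfusionCounts",
    slots = c(tp = "integer", tn = "integer", fp = "integer", fn = "integer")
)

setValidity("ConfusionCounts", function(object) {
    counts <- c(object@tp, object@tn, object@fp, object@fn)
    if (length(counts) != 4L || any(is.na(counts)) || any(counts < 0L))
        "tp, tn, fp, fn must be single nonnegative integers"
    else TRUE
})

#' Nine confusion-matrix performance metrics on the percent scale
#'
#' Accuracy, sensitivity (= recall), specificity, positive predictivity
#' (= precision), F1, fall-out (100 - specificity) and miss rate
#' (100 - sensitivity), all in percent. Metrics with a zero denominator are
#' \code{NA}.
#'
#' @slot metrics named numeric vector of the nine metrics.
#' @slot counts the [ConfusionCounts-class] the metrics derive from.
#' @export
setClass("MetricsReport",
    slots = c(metrics = "numeric", counts = "ConfusionCounts")
)

.METRIC_NAMES <- c("accuracy", "sensitivity", "specificity",
                   "positivePredictivity", "recall", "precision",
                   "f1", "fallOut", "missRate")

setValidity("MetricsReport", function(object) {
    msg <- character()
    if (!identical(names(object@metrics), .METRIC_NAMES))
        msg <- c(msg, "metrics must be the nine named metrics in canonical order")
    ok <- !is.na(object@metrics)
    if (any(object@metrics[ok] < -1e-9 | object@metrics[ok] > 100 + 1e-9))
        msg <- c(msg, "metrics must lie in [0, 100]")
    if (length(msg)) msg else TRUE
})

#' A fitted seizure/normal classifier
#'
#' Wraps one of the seven supported learners together with the
#' standardisation (per-feature center/scale) estimated on its training
#' table. Prediction always re-applies the stored scaling; it is never
#' re-estimated on test data.
#'
#' @slot name classifier name, one of
#'   \code{svm, ensemble, knn, lda, logistic_regression, decision_tree,
#'   naive_bayes}.
#' @slot fit the fitted model object (learner specific).
#' @slot hyperparameters named list of the hyperparameters used.
#' @slot center,scale numeric vectors of per-feature z-score parameters.
#' @slot featureNames the eleven feature columns seen at fit time.
#' @slot seed integer seed that governed stochastic fitting.
#' @seealso [trainClassifier()], [predictLabels()].
#' @export
setClass("SeizureClassifier",
    slots = c(
        name = "character",
        fit = "ANY",
        hyperparameters = "list",
        center = "numeric",
        scale = "numeric",
        featureNames = "character",
        seed = "integer"
    )
)

#' Configuration of the synthetic EEG generator
#'
#' Describes one synthetic multichannel record: band-limited colored
#' background noise on every channel, plus an additive rhythmic spike-wave
#' component on \code{burstChannels} inside each seizure interval, so that
#' ictal variance on burst channels exceeds interictal variance in
#' expectation.
#'
#' @slot nChannels number of channels (default 23).
#' @slot fs sampling rate in Hz (default 256).
#' @slot durationS record duration in seconds.
#' @slot seizureIntervals data.frame with \code{start_s}, \code{end_s}.
#' @slot burstChannels integer channel indices carrying the ictal bursts.
#' @slot amplitudeFactor ictal amplitude multiplier, >= 1. The spike-wave
#'   component has the RMS of a sinusoid whose peak amplitude is
#'   \code{amplitudeFactor * backgroundSd}.
#' @slot backgroundSd per-channel background standard deviation, microvolts
#'   (default 50).
#' @slot spikeFreqHz spike-wave fundamental frequency (default 3 Hz).
#' @slot seed integer seed; all randomness derives from it.
#' @seealso [synthConfig()], [simulateRecord()].
#' @export
setClass("SynthConfig",
    slots = c(
        nChannels = "integer",
        fs = "numeric",
        durationS = "numeric",
        seizureIntervals = "data.frame",
        burstChannels = "integer",
        amplitudeFactor = "numeric",
        backgroundSd = "numeric",
        spikeFreqHz = "numeric",
        seed = "integer"
    )
)

setValidity("SynthConfig", function(object) {
    msg <- character()
    if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
    if (object@fs <= 0) msg <- c(msg, "fs must be positive")
    if (object@durationS <= 0) msg <- c(msg, "durationS must be positive")
    if (object@amplitudeFactor < 1)
        msg <- c(msg, "amplitudeFactor must be >= 1")
    if (object@backgroundSd <= 0) msg <- c(msg, "backgroundSd must be positive")
    if (object@spikeFreqHz <= 0) msg <- c(msg, "spikeFreqHz must be positive")
    if (length(object@burstChannels) &&
        (any(object@burstChannels < 1L) ||
         any(object@burstChannels > object@nChannels)))
        msg <- c(msg, "burstChannels must be channel indices of the record")
    iv <- object@seizureIntervals
    if (nrow(iv)) {
        if (any(iv$start_s < 0) || any(iv$end_s <= iv$start_s) ||
            any(iv$end_s > object@durationS + 1e-9))
            msg <- c(msg, "seizure intervals must be valid and within the record")
        o <- order(iv$start_s)
        if (nrow(iv) > 1L && any(iv$start_s[o][-1L] < iv$end_s[o][-nrow(iv)]))
            msg <- c(msg, "seizure intervals must be disjoint")
    }
    if (length(msg)) msg else TRUE
})
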