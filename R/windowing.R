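## Epoch extraction under the two testing protocols.
##
## A window is labelled "seizure" iff it lies entirely inside an annotated
## interval and "normal" iff it lies entirely outside all of them; windows
## straddling a boundary are never produced.

## Sorted annotation intervals and their complement within [0, duration].
.segments <- function(record) {
    dur <- recordDuration(record)
    ann <- record@annotations
    if (nrow(ann) == 0L)
        return(list(seizure = data.frame(start_s = numeric(), end_s = numeric()),
                    normal = data.frame(start_s = 0, end_s = dur)))
    ann <- ann[order(ann$start_s), , drop = FALSE]
    gaps <- data.frame(start_s = c(0, ann$end_s),
                       end_s = c(ann$start_s, dur))
    gaps <- gaps[gaps$end_s - gaps$start_s > 1e-12, , drop = FALSE]
    list(seizure = ann, normal = gaps)
}

## Packed grid of window starts inside one segment: start, start+w, ...
.packedStarts <- function(seg, w) {
    unlist(lapply(seq_len(nrow(seg)), function(i) {
        nfit <- floor((seg$end_s[i] - seg$start_s[i]) / w + 1e-9)
        if (nfit < 1L) return(numeric())
        seg$start_s[i] + (seq_len(nfit) - 1L) * w
    }))
}

.cutWindow <- function(record, startS, wSamples, label) {
    i0 <- round(startS * record@fs)
    cols <- (i0 + 1L):(i0 + wSamples)
    new("EEGWindow", signal = record@signal[, cols, drop = FALSE],
        label = label, recordId = record@recordId,
        startS = startS, fs = record@fs)
}

#' Cut a record into consecutive labelled epochs (continuous protocol)
#'
#' Every annotated seizure interval is tiled into consecutive non-overlapping
#' windows starting at the interval start (a partial trailing remainder is
#' dropped) and labelled \code{"seizure"}; the non-annotated remainder of the
#' record is tiled the same way and labelled \code{"normal"}. A 30-s event
#' tiled at 10 s therefore yields exactly three seizure epochs.
#'
#' @param record an [EEGRecord-class].
#' @param windowSeconds epoch length in seconds (default 10).
#' @return list of [EEGWindow-class] objects ordered by start time.
#' @seealso [windowRandom()]
#' @export
windowContinuous <- function(record, windowSeconds = 10) {
    stopifnot(is(record, "EEGRecord"), windowSeconds > 0)
    w <- windowSeconds
    wSamples <- as.integer(round(w * record@fs))
    seg <- .segments(record)
    starts <- c(.packedStarts(seg$seizure, w), .packedStarts(seg$normal, w))
    labels <- rep(c("seizure", "normal"),
                  c(length(.packedStarts(seg$seizure, w)),
                    length(.packedStarts(seg$normal, w))))
    o <- order(starts)
    mapply(function(s, l) .cutWindow(record, s, wSamples, l),
           starts[o], labels[o], SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Draw random non-overlapping labelled epochs (random protocol)
#'
#' Draws \code{nPerClass} seizure and \code{nPerClass} normal epochs without
#' overlap, uniformly at random among the window-aligned placements that fit
#' entirely inside (seizure) or entirely outside (normal) the annotated
#' intervals. Placements within a segment are aligned to its start in steps
#' of one window length, which guarantees non-overlap and makes the per-class
#' capacity exactly \code{sum(floor(segment_length / windowSeconds))}.
#' Reproducible for a fixed seed.
#'
#' @param record an [EEGRecord-class].
#' @param windowSeconds epoch length in seconds (default 10).
#' @param nPerClass number of epochs to draw from each class.
#' @param seed integer seed.
#' @return list of [EEGWindow-class] objects, seizure epochs first.
#' @seealso [windowContinuous()]
#' @export
windowRandom <- function(record, windowSeconds = 10, nPerClass, seed = 1L) {
    stopifnot(is(record, "EEGRecord"), windowSeconds > 0, nPerClass >= 1L)
    w <- windowSeconds
    wSamples <- as.integer(round(w * record@fs))
    seg <- .segments(record)
    out <- list()
    for (cls in c("seizure", "normal")) {
        starts <- .packedStarts(seg[[cls]], w)
        if (length(starts) < nPerClass)
            .stopf(paste0("capacity error: only %d disjoint %g-s '%s' windows",
                          " fit this record (%d requested)"),
                   length(starts), w, cls, nPerClass)
        pick <- .withSeed(seed + match(cls, .LABEL_LEVELS),
                          sort(sample(starts, nPerClass)))
        out <- c(out, lapply(pick, function(s)
            .cutWindow(record, s, wSamples, cls)))
    }
    out
}
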