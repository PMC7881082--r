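#' Per-channel amplitude variance of an epoch
#'
#' For each channel \eqn{c} with samples \eqn{X_c(1..K)} returns the
#' population variance \eqn{(1/K) \sum_i (X_c(i) - \mu_c)^2} (microvolts^2).
#' The population normalisation (1/K) is used here; the feature-side
#' variance uses 1/(N-1). The channel ranking is invariant to that factor,
#' so both conventions are kept as defined.
#'
#' @param x an [EEGWindow-class], [EEGRecord-class], or a channels x samples
#'   numeric matrix.
#' @return numeric vector of per-channel variances.
#' @seealso [selectTopK()]
#' @export
channelVariance <- function(x) {
    sig <- if (is(x, "EEGWindow") || is(x, "EEGRecord")) eegSignal(x)
           else as.matrix(x)
    if (ncol(sig) < 1L)
        .stopf("channelVariance: channels must have at least one sample")
    mu <- rowMeans(sig)
    rowMeans((sig - mu)^2)
}

#' Select the k highest-variance channels
#'
#' Ranks channels by amplitude variance and keeps the \code{k} largest, in
#' descending variance order; ties are broken toward the lower channel
#' index. Three channels suffice for seizure detection without loss of
#' performance, so \code{k = 3} is the default throughout the pipeline.
#'
#' @param variances numeric vector of per-channel variances (from
#'   [channelVariance()]), or an [EEGWindow-class] from which they are
#'   computed.
#' @param k number of channels to keep (default 3). If \code{k} exceeds the
#'   number of channels, all channels are returned with a warning.
#' @return a [ChannelRanking-class].
#' @examples
#' selectTopK(c(10, 50, 30, 40), k = 2)  # channels 2 and 4
#' @export
selectTopK <- function(variances, k = 3L) {
    if (is(variances, "EEGWindow")) variances <- channelVariance(variances)
    stopifnot(is.numeric(variances), length(variances) >= 1L)
    k <- as.integer(k)
    if (k < 1L) .stopf("selectTopK: k must be >= 1")
    if (k > length(variances)) {
        .warnf("selectTopK: k = %d exceeds the %d available channels; keeping all",
               k, length(variances))
        k <- length(variances)
    }
    ord <- order(-variances, seq_along(variances))
    new("ChannelRanking", variances = as.numeric(variances),
        selected = as.integer(ord[seq_len(k)]), k = k)
}

#' Majority-vote channel selection over many epochs
#'
#' Alternative per-record mode: each epoch votes for its top-k channels and
#' the k most frequently selected channels win (ties toward the lower
#' index). The default pipeline recomputes the selection per epoch; this
#' mode is offered for users who want one fixed montage per record.
#'
#' @param windows list of [EEGWindow-class] objects.
#' @param k number of channels to keep (default 3).
#' @return integer vector of the k winning channel indices.
#' @export
selectTopKMajority <- function(windows, k = 3L) {
    stopifnot(length(windows) >= 1L)
    votes <- table(unlist(lapply(windows, function(w)
        selectedChannels(selectTopK(channelVariance(w), k)))))
    idx <- as.integer(names(votes))
    ord <- order(-as.integer(votes), idx)
    sort(idx[ord][seq_len(min(k, length(idx)))])
}

#' Serialise a channel ranking to CSV
#'
#' Writes one row per channel: label, variance, and whether it was selected.
#'
#' @param ranking a [ChannelRanking-class].
#' @param path output CSV path.
#' @param channelNames optional channel labels; defaults to \code{CH1..CHn}.
#' @export
writeChannelRanking <- function(ranking, path, channelNames = NULL) {
    v <- channelVariances(ranking)
    if (is.null(channelNames)) channelNames <- paste0("CH", seq_along(v))
    df <- data.frame(channel = channelNames, variance = v,
                     selected = seq_along(v) %in% selectedChannels(ranking))
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}
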