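#' Extract the eleven features of one channel signal
#'
#' Computes the feature vector used throughout the pipeline from a single
#' channel of one epoch:
#' \describe{
#'   \item{STD}{sample standard deviation, 1/(N-1) normalisation (uV).}
#'   \item{Mean}{arithmetic mean (uV).}
#'   \item{Max, Min}{extreme sample values (uV).}
#'   \item{Var}{\code{STD^2} (uV^2).}
#'   \item{Med}{sample median (uV).}
#'   \item{SKW}{skewness, third standardised population moment
#'     (dimensionless).}
#'   \item{ENT}{Shannon entropy (natural log by default) of the normalised
#'     amplitude histogram over \code{entropyBins} equal-width bins.}
#'   \item{KRT}{kurtosis, fourth standardised population moment,
#'     non-excess (Gaussian = 3).}
#'   \item{MOM}{central population moment of order \code{momentOrder}
#'     (default 4, uV^4), so \code{MOM = KRT * sigma_pop^4}.}
#'   \item{POW}{spectral power: \code{sum(F * Conj(F))} over the
#'     unnormalised DFT \code{F} of the signal, which by Parseval's theorem
#'     equals \code{N * sum(x^2)}. Other DFT normalisations would change
#'     this value and are deliberately not used.}
#' }
#' A zero-variance signal has undefined skewness and kurtosis; both are
#' returned as 0 with a warning.
#'
#' @param channelSignal numeric vector of at least 4 samples (microvolts).
#' @param entropyBins number of amplitude histogram bins (default 100).
#' @param entropyBase logarithm base for the entropy (default \code{exp(1)}).
#' @param momentOrder order of the central moment feature (default 4).
#' @return named numeric vector with elements
#'   \code{STD, Mean, Max, Min, Var, Med, SKW, ENT, KRT, MOM, POW}.
#' @examples
#' x <- sin(seq(0, 20 * pi, length.out = 2560)) * 100
#' extractFeatures(x)[c("STD", "POW")]
#' @export
extractFeatures <- function(channelSignal, entropyBins = 100L,
                            entropyBase = exp(1), momentOrder = 4L) {
    x <- as.numeric(channelSignal)
    n <- length(x)
    if (n < 4L)
        .stopf("extractFeatures: at least 4 samples are required (got %d)", n)
    mu <- mean(x)
    s <- stats::sd(x)
    m2 <- .popMoment(x, 2L)
    if (m2 > 0) {
        skw <- .popMoment(x, 3L) / m2^1.5
        krt <- .popMoment(x, 4L) / m2^2
    } else {
        .warnf("extractFeatures: zero-variance signal; skewness and kurtosis set to 0")
        skw <- krt <- 0
    }
    mom <- .popMoment(x, momentOrder)
    rng <- range(x)
    ent <- if (rng[2L] > rng[1L]) {
        counts <- tabulate(pmin(
            floor((x - rng[1L]) / (rng[2L] - rng[1L]) * entropyBins) + 1L,
            entropyBins), nbins = entropyBins)
        p <- counts[counts > 0L] / n
        -sum(p * log(p, base = entropyBase))
    } else 0
    f <- stats::fft(x)
    pow <- sum(Re(f * Conj(f)))
    c(STD = s, Mean = mu, Max = rng[2L], Min = rng[1L], Var = s^2,
      Med = stats::median(x), SKW = skw, ENT = ent, KRT = krt,
      MOM = mom, POW = pow)
}

#' Average feature vectors across channels
#'
#' Element-wise arithmetic mean of the eleven features across the selected
#' channels of one epoch, collapsing \code{11 x k} values into the single
#' 11-value classifier input row.
#'
#' @param vectors a list of named feature vectors (from
#'   [extractFeatures()]), or a matrix/data.frame with one such vector per
#'   row.
#' @return named numeric vector of the eleven averaged features.
#' @examples
#' averageFeatures(rbind(c(STD = 463.10), c(STD = 395.41), c(STD = 388.61)))
#' @export
averageFeatures <- function(vectors) {
    if (length(vectors) < 1L)
        .stopf("averageFeatures: at least one feature vector is required")
    if (is.list(vectors) && !is.data.frame(vectors))
        vectors <- do.call(rbind, vectors)
    vectors <- as.matrix(vectors)
    if (nrow(vectors) < 1L)
        .stopf("averageFeatures: at least one feature vector is required")
    colMeans(vectors)
}

#' Build the classifier-facing feature table from labelled epochs
#'
#' For each epoch: rank its channels by variance, keep the top \code{k}
#' (default 3), extract the eleven features from each selected channel,
#' average them element-wise, and attach the epoch label. One row per epoch.
#'
#' @param windows list of [EEGWindow-class] objects.
#' @param k number of channels to select per epoch (default 3).
#' @param entropyBins,entropyBase,momentOrder passed to [extractFeatures()].
#' @return a [FeatureTable-class] with one row per epoch.
#' @seealso [trainClassifier()], [crossValidate()]
#' @export
buildFeatureTable <- function(windows, k = 3L, entropyBins = 100L,
                              entropyBase = exp(1), momentOrder = 4L) {
    if (length(windows) < 1L)
        .stopf("buildFeatureTable: at least one window is required")
    rows <- lapply(windows, function(w) {
        ranking <- selectTopK(channelVariance(w), k)
        sig <- eegSignal(w)
        feats <- lapply(selectedChannels(ranking), function(ch)
            extractFeatures(sig[ch, ], entropyBins = entropyBins,
                            entropyBase = entropyBase,
                            momentOrder = momentOrder))
        averageFeatures(feats)
    })
    features <- as.data.frame(do.call(rbind, rows))
    featureTable(
        features,
        state = vapply(windows, windowLabel, character(1L)),
        windowInfo = data.frame(
            record_id = vapply(windows, recordId, character(1L)),
            start_s = vapply(windows, windowStart, numeric(1L))))
}

#' Read and write feature tables as CSV
#'
#' The on-disk layout has the eleven feature columns in canonical order
#' followed by a \code{State} column coded \code{"s"} (seizure) /
#' \code{"n"} (normal), plus optional \code{record_id}/\code{start_s}
#' provenance columns. Lines starting with \code{#} carry embedded run
#' metadata and are skipped on read.
#'
#' @param x a [FeatureTable-class].
#' @param path CSV file path.
#' @param comment optional character vector written as leading \code{#}
#'   metadata lines (e.g. the resolved run configuration).
#' @export
writeFeatureTable <- function(x, path, comment = NULL) {
    stopifnot(is(x, "FeatureTable"))
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(comment)) writeLines(paste0("# ", comment), con)
    df <- cbind(x@features,
                State = c(seizure = "s", normal = "n")[x@state],
                x@windowInfo)
    utils::write.csv(format(df, trim = TRUE, digits = 15), con,
                     row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeFeatureTable
#' @return \code{readFeatureTable}: a [FeatureTable-class].
#' @export
readFeatureTable <- function(path) {
    df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
    if (!all(.FEATURE_NAMES %in% names(df)) || !("State" %in% names(df)))
        .stopf("feature table %s must have columns %s and State", path,
               paste(.FEATURE_NAMES, collapse = ","))
    state <- c(s = "seizure", n = "normal")[as.character(df$State)]
    if (anyNA(state))
        .stopf("feature table %s: State must be coded 's' or 'n'", path)
    info <- if (all(c("record_id", "start_s") %in% names(df)))
        data.frame(record_id = as.character(df$record_id),
                   start_s = as.numeric(df$start_s))
    else NULL
    featureTable(df[, .FEATURE_NAMES], state = unname(state),
                 windowInfo = info)
}
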