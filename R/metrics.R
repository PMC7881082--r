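#' Confusion counts of predicted vs true labels
#'
#' Seizure is the positive class: TP = seizure predicted seizure,
#' FN = seizure predicted normal, TN = normal predicted normal,
#' FP = normal predicted seizure.
#'
#' @param yTrue,yPred character vectors of \code{"seizure"}/\code{"normal"}
#'   labels, equal length.
#' @return a [ConfusionCounts-class].
#' @seealso [computeMetrics()]
#' @export
confusionCounts <- function(yTrue, yPred) {
    if (length(yTrue) != length(yPred))
        .stopf("confusionCounts: label vectors differ in length (%d vs %d)",
               length(yTrue), length(yPred))
    if (!all(c(yTrue, yPred) %in% .LABEL_LEVELS))
        .stopf("confusionCounts: labels must be 'seizure' or 'normal'")
    confusionCountsFromValues(
        tp = sum(yTrue == "seizure" & yPred == "seizure"),
        tn = sum(yTrue == "normal" & yPred == "normal"),
        fp = sum(yTrue == "normal" & yPred == "seizure"),
        fn = sum(yTrue == "seizure" & yPred == "normal"))
}

#' The nine performance metrics, on the percent scale
#'
#' From confusion counts with seizure positive:
#' accuracy = (TP+TN)/(TP+FP+TN+FN), sensitivity = recall = TP/(TP+FN),
#' specificity = TN/(TN+FP), positive predictivity = precision =
#' TP/(TP+FP), F1 = 2*precision*recall/(precision+recall),
#' fall-out = FP/(TN+FP) = 100 - specificity, and miss rate = FN/(TP+FN)
#' = 100 - sensitivity; all multiplied by 100. Fall-out and miss rate are
#' reported on the percent scale like every other metric so that the full
#' suite is directly comparable. A metric whose denominator is zero is
#' returned as \code{NA} with a warning, never silently as 0.
#'
#' @param counts a [ConfusionCounts-class].
#' @return a [MetricsReport-class].
#' @examples
#' computeMetrics(confusionCountsFromValues(tp = 42, tn = 31, fp = 9, fn = 0))
#' @export
computeMetrics <- function(counts) {
    stopifnot(is(counts, "ConfusionCounts"))
    tp <- counts@tp; tn <- counts@tn; fp <- counts@fp; fn <- counts@fn
    frac <- function(num, den, what) {
        if (den == 0L) {
            .warnf("computeMetrics: %s undefined (zero denominator)", what)
            return(NA_real_)
        }
        num / den * 100
    }
    accuracy <- frac(tp + tn, tp + fp + tn + fn, "accuracy")
    sensitivity <- frac(tp, tp + fn, "sensitivity")
    specificity <- frac(tn, tn + fp, "specificity")
    precision <- frac(tp, tp + fp, "positive predictivity")
    f1 <- if (is.na(precision) || is.na(sensitivity)) NA_real_
          else if (precision + sensitivity == 0) {
              .warnf("computeMetrics: f1 undefined (precision + recall = 0)")
              NA_real_
          } else 2 * precision * sensitivity / (precision + sensitivity)
    metrics <- c(accuracy = accuracy, sensitivity = sensitivity,
                 specificity = specificity,
                 positivePredictivity = precision, recall = sensitivity,
                 precision = precision, f1 = f1,
                 fallOut = if (is.na(specificity)) NA_real_ else 100 - specificity,
                 missRate = if (is.na(sensitivity)) NA_real_ else 100 - sensitivity)
    new("MetricsReport", metrics = metrics, counts = counts)
}

#' Stratified k-fold assignment
#'
#' Partitions the rows of a feature table into \code{K} folds so that fold
#' sizes differ by at most one, both overall and within each class
#' (stratification keeps the seizure/normal balance of every fold).
#' Seeded and reproducible. \code{K = nrow} gives leave-one-out.
#'
#' @param table a [FeatureTable-class] (or a character label vector).
#' @param K number of folds (default 5).
#' @param seed integer seed.
#' @return integer vector of fold indices in \code{1..K}, one per row.
#' @export
kfoldAssign <- function(table, K = 5L, seed = 1L) {
    state <- if (is(table, "FeatureTable")) stateLabels(table)
             else as.character(table)
    K <- as.integer(K)
    if (K < 2L) .stopf("kfoldAssign: K must be >= 2")
    if (K == length(state))      # leave-one-out: one row per fold
        return(.withSeed(seed, sample(K)))
    counts <- table(state)
    if (any(counts < K))
        .stopf("kfoldAssign: class '%s' has %d rows, fewer than K = %d",
               names(counts)[which.min(counts)], min(counts), K)
    fold <- integer(length(state))
    offset <- 0L
    for (cls in names(counts)) {
        idx <- which(state == cls)
        idx <- .withSeed(seed + offset, sample(idx))
        ## round-robin starting where the previous class's extras stopped,
        ## so remainders spread across folds and global sizes differ by <= 1
        fold[idx] <- ((seq_along(idx) - 1L + offset) %% K) + 1L
        offset <- (offset + length(idx)) %% K
    }
    fold
}

setClass("CrossValidationResult",
    slots = c(
        classifier = "character",
        pooled = "MetricsReport",
        perFold = "list",
        folds = "integer",
        K = "integer",
        seed = "integer"
    )
)

setMethod("show", "CrossValidationResult", function(object) {
    cat(sprintf("%d-fold cross-validation of '%s' (seed %d), pooled:\n",
                object@K, object@classifier, object@seed))
    show(object@pooled)
})

#' K-fold cross-validation of one classifier
#'
#' Assigns stratified folds, then for each fold trains on the other
#' \code{K - 1} folds and predicts the held-out fold. The pooled report is
#' computed from the sum of the per-fold confusion counts, so every row is
#' scored exactly once.
#'
#' @param name classifier name (see [classifierNames()]).
#' @param table a [FeatureTable-class].
#' @param K number of folds (default 5).
#' @param seed integer seed governing fold assignment and stochastic
#'   learners.
#' @param hyperparameters passed to [trainClassifier()].
#' @return a \code{CrossValidationResult}: pooled [MetricsReport-class]
#'   (slot \code{pooled}), per-fold reports (slot \code{perFold}), and the
#'   fold assignment (slot \code{folds}).
#' @export
crossValidate <- function(name, table, K = 5L, seed = 1L,
                          hyperparameters = list()) {
    stopifnot(is(table, "FeatureTable"))
    K <- as.integer(K)
    folds <- kfoldAssign(table, K = K, seed = seed)
    state <- stateLabels(table)
    perFold <- vector("list", K)
    tot <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
    for (kf in seq_len(K)) {
        holdOut <- folds == kf
        model <- trainClassifier(name, table[!holdOut], seed = seed + kf,
                                 hyperparameters = hyperparameters)
        pred <- predictLabels(model, table[holdOut])
        cc <- confusionCounts(state[holdOut], pred)
        perFold[[kf]] <- suppressWarnings(computeMetrics(cc))
        tot <- tot + countValues(cc)
    }
    pooled <- computeMetrics(confusionCountsFromValues(
        tot[["tp"]], tot[["tn"]], tot[["fp"]], tot[["fn"]]))
    new("CrossValidationResult", classifier = name, pooled = pooled,
        perFold = perFold, folds = folds, K = K, seed = as.integer(seed))
}

#' Remove abnormal training rows (noise filter)
#'
#' Data-observation filter for training tables: using one designated
#' feature (default \code{"Mean"}, the one used to eyeball class spread),
#' a normal-labelled row lying deep inside the seizure side of that feature
#' — more than \code{zThreshold} robust standard deviations (MAD) from the
#' normal-class median toward the seizure class — is treated as a noise
#' sample and removed, and symmetrically for seizure rows on the normal
#' side. The direction is determined from the two class medians, so the
#' rule works whichever way the feature separates. May remove zero rows.
#'
#' @param table a [FeatureTable-class] with at least 3 rows per class.
#' @param zThreshold robust z-score cutoff (default 3).
#' @param feature feature column used for the screen (default \code{"Mean"}).
#' @return list with elements \code{table} (the filtered
#'   [FeatureTable-class]) and \code{removed} (data.frame of removed rows:
#'   index, state, feature value, robust z).
#' @export
filterAbnormal <- function(table, zThreshold = 3, feature = "Mean") {
    stopifnot(is(table, "FeatureTable"))
    if (!(feature %in% .FEATURE_NAMES))
        .stopf("filterAbnormal: unknown feature '%s'", feature)
    state <- stateLabels(table)
    if (any(table(state) < 3L))
        .stopf("filterAbnormal: at least 3 rows per class are required")
    x <- featureMatrix(table)[, feature]
    medS <- stats::median(x[state == "seizure"])
    medN <- stats::median(x[state == "normal"])
    madS <- stats::mad(x[state == "seizure"])
    madN <- stats::mad(x[state == "normal"])
    madS <- if (madS > 0) madS else stats::sd(x[state == "seizure"])
    madN <- if (madN > 0) madN else stats::sd(x[state == "normal"])
    dir <- sign(medS - medN)
    if (dir == 0) dir <- 1
    z <- numeric(length(x))
    z[state == "normal"] <- dir * (x[state == "normal"] - medN) / madN
    z[state == "seizure"] <- dir * (medS - x[state == "seizure"]) / madS
    drop <- z > zThreshold
    removed <- data.frame(row = which(drop), state = state[drop],
                          value = x[drop], z = z[drop])
    list(table = table[!drop], removed = removed)
}

#' Serialise metric results to JSON
#'
#' Writes counts and the nine metrics (plus, for cross-validation results,
#' per-fold counts/metrics and the fold assignment) together with any
#' resolved configuration, so every output file records how it was made.
#'
#' @param x a [MetricsReport-class] or \code{CrossValidationResult}.
#' @param path output JSON path.
#' @param config optional named list of resolved run configuration to embed.
#' @export
writeMetricsJSON <- function(x, path, config = NULL) {
    asList <- function(rep) list(counts = as.list(countValues(rep@counts)),
                                 metrics = as.list(metricValues(rep)))
    payload <- if (is(x, "CrossValidationResult")) {
        list(classifier = x@classifier, K = x@K, seed = x@seed,
             pooled = asList(x@pooled),
             perFold = lapply(x@perFold, asList),
             folds = x@folds)
    } else if (is(x, "MetricsReport")) {
        asList(x)
    } else .stopf("writeMetricsJSON: unsupported object of class %s", class(x))
    if (!is.null(config)) payload$config <- config
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    invisible(path)
}

#' Format several metric reports as an evaluation text table
#'
#' Rows are TP/TN/FP/FN and the seven headline metrics; one column per
#' classifier. Used by the command-line interface to print evaluation
#' summaries.
#'
#' @param reports named list of [MetricsReport-class] objects (names =
#'   classifier names).
#' @return character vector of formatted lines.
#' @export
formatMetricsTable <- function(reports) {
    stopifnot(length(reports) >= 1L)
    rows <- c("TP", "TN", "FP", "FN", "Accuracy", "Sensitivity",
              "Specificity", "PositivePre", "F1", "FallOut", "MisRate")
    keys <- c("accuracy", "sensitivity", "specificity",
              "positivePredictivity", "f1", "fallOut", "missRate")
    cols <- vapply(reports, function(rep) {
        cnt <- countValues(rep@counts)
        met <- metricValues(rep)[keys]
        c(sprintf("%d", cnt),
          ifelse(is.na(met), "NA", sprintf("%.5f", met)))
    }, character(length(rows)))
    cols <- cbind(Metric = rows, cols)
    widths <- pmax(nchar(colnames(cols)), apply(nchar(cols), 2L, max))
    fmtRow <- function(vals) paste(mapply(formatC, vals, width = widths),
                                   collapse = "  ")
    c(fmtRow(colnames(cols)), apply(cols, 1L, fmtRow))
}
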