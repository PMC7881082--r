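.CLASSIFIER_NAMES <- c("svm", "ensemble", "knn", "lda",
                       "logistic_regression", "decision_tree", "naive_bayes")

.defaultHyperparameters <- function(name) {
    switch(name,
        svm = list(kernel = "radial", cost = 1),
        ensemble = list(ntree = 100L),          # bagged CART: mtry = all 11
        knn = list(k = 5L),                     # odd, avoids voting ties
        lda = list(),
        logistic_regression = list(threshold = 0.5),
        decision_tree = list(split = "gini", cp = 0),
        naive_bayes = list())                   # Gaussian class-conditionals
}

.scaleFeatures <- function(m, center, scale) {
    scale[scale == 0] <- 1
    sweep(sweep(m, 2L, center), 2L, scale, "/")
}

#' Train one of the seven supported classifiers
#'
#' Fits a seizure/normal classifier on an averaged feature table. Features
#' are standardised (z-score) with training-set statistics before fitting;
#' the same center/scale is stored in the model and re-applied at prediction
#' time. The features span ten orders of magnitude (skewness near 0.1,
#' spectral power near 1e12), so standardisation is required for the
#' distance- and margin-based learners to behave sensibly. Stochastic
#' learners are fully governed by \code{seed}.
#'
#' Supported names and default hyperparameters (all overridable via
#' \code{hyperparameters}): \code{svm} (RBF kernel, C = 1), \code{ensemble}
#' (bagged decision trees, 100 learners), \code{knn} (k = 5), \code{lda},
#' \code{logistic_regression} (threshold 0.5), \code{decision_tree} (Gini,
#' unlimited depth), \code{naive_bayes} (Gaussian).
#'
#' @param name classifier name, one of
#'   \code{svm, ensemble, knn, lda, logistic_regression, decision_tree,
#'   naive_bayes}.
#' @param table a [FeatureTable-class] with at least 2 rows per class.
#' @param seed integer seed for stochastic learners.
#' @param hyperparameters named list overriding the defaults above.
#' @return a [SeizureClassifier-class].
#' @seealso [predictLabels()], [crossValidate()]
#' @export
trainClassifier <- function(name, table, seed = 1L, hyperparameters = list()) {
    if (!(name %in% .CLASSIFIER_NAMES))
        .stopf("unknown classifier '%s'; valid names: %s", name,
               paste(.CLASSIFIER_NAMES, collapse = ", "))
    stopifnot(is(table, "FeatureTable"))
    state <- stateLabels(table)
    if (length(unique(state)) < 2L)
        .stopf("training table must contain both classes (got only '%s')",
               unique(state))
    if (min(table(state)) < 2L)
        .stopf("training table needs at least 2 rows per class")
    hp <- utils::modifyList(.defaultHyperparameters(name), hyperparameters)
    m <- featureMatrix(table)
    center <- colMeans(m)
    scale <- apply(m, 2L, stats::sd)
    z <- .scaleFeatures(m, center, scale)
    y <- factor(state, levels = .LABEL_LEVELS)
    fit <- .withSeed(seed, switch(name,
        svm = e1071::svm(x = z, y = y, kernel = hp$kernel, cost = hp$cost,
                         scale = FALSE),
        ensemble = randomForest::randomForest(x = z, y = y,
                                              ntree = hp$ntree,
                                              mtry = ncol(z)),
        knn = list(train = z, cl = y, k = hp$k),
        lda = MASS::lda(z, grouping = y),
        logistic_regression = {
            df <- data.frame(z, y = factor(state,
                                           levels = c("normal", "seizure")))
            suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
        },
        decision_tree = {
            df <- data.frame(z, y = y)
            rpart::rpart(y ~ ., data = df, method = "class",
                         parms = list(split = hp$split),
                         control = rpart::rpart.control(
                             cp = hp$cp, minsplit = 2L, minbucket = 1L,
                             xval = 0L))
        },
        naive_bayes = e1071::naiveBayes(x = as.data.frame(z), y = y)))
    new("SeizureClassifier", name = name, fit = fit, hyperparameters = hp,
        center = center, scale = scale, featureNames = colnames(m),
        seed = as.integer(seed))
}

#' Predict seizure/normal labels for a feature table
#'
#' Applies the stored fit-time standardisation (never re-estimated) and
#' returns one binary label per row. The output is always
#' \code{"seizure"}/\code{"normal"}; there are no abstentions.
#'
#' @param model a [SeizureClassifier-class].
#' @param table a [FeatureTable-class] with the same eleven feature columns
#'   seen at fit time.
#' @return character vector of labels, one per row of \code{table}.
#' @export
predictLabels <- function(model, table) {
    stopifnot(is(model, "SeizureClassifier"), is(table, "FeatureTable"))
    m <- featureMatrix(table)
    if (nrow(m) == 0L) return(character())
    missing <- setdiff(model@featureNames, colnames(m))
    extra <- setdiff(colnames(m), model@featureNames)
    if (length(missing) || length(extra))
        .stopf("feature schema mismatch: missing [%s], unexpected [%s]",
               paste(missing, collapse = ","), paste(extra, collapse = ","))
    z <- .scaleFeatures(m[, model@featureNames, drop = FALSE],
                        model@center, model@scale)
    hp <- model@hyperparameters
    pred <- switch(model@name,
        svm = as.character(stats::predict(model@fit, z)),
        ensemble = as.character(stats::predict(model@fit, z)),
        knn = .withSeed(model@seed,
            as.character(class::knn(model@fit$train, z, model@fit$cl,
                                    k = model@fit$k))),
        lda = as.character(stats::predict(model@fit, z)$class),
        logistic_regression = {
            p <- stats::predict(model@fit, newdata = as.data.frame(z),
                                type = "response")
            ifelse(p > hp$threshold, "seizure", "normal")
        },
        decision_tree = as.character(
            stats::predict(model@fit, newdata = as.data.frame(z),
                           type = "class")),
        naive_bayes = as.character(
            stats::predict(model@fit, newdata = as.data.frame(z))))
    unname(pred)
}

#' Persist and restore a trained classifier
#'
#' The stored object is self-describing: classifier name, hyperparameters,
#' feature scaling, seed, and the fitted state.
#'
#' @param model a [SeizureClassifier-class].
#' @param path file path (RDS).
#' @export
saveClassifier <- function(model, path) {
    stopifnot(is(model, "SeizureClassifier"))
    saveRDS(model, path)
    invisible(path)
}

#' @rdname saveClassifier
#' @return \code{readClassifier}: the restored [SeizureClassifier-class].
#' @export
readClassifier <- function(path) {
    model <- readRDS(path)
    if (!is(model, "SeizureClassifier"))
        .stopf("%s does not contain a SeizureClassifier", path)
    model
}

#' Names of the seven supported classifiers
#' @return character vector of valid classifier names.
#' @export
classifierNames <- function() .CLASSIFIER_NAMES
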