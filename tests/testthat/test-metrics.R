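test_that("confusion counts treat seizure as the positive class", {
    yt <- rep(c("seizure", "normal"), each = 5L)
    cc <- confusionCounts(yt, yt)
    expect_equal(countValues(cc), c(tp = 5L, tn = 5L, fp = 0L, fn = 0L))
    cc2 <- confusionCounts(yt, rep("normal", 10L))
    expect_equal(countValues(cc2), c(tp = 0L, tn = 5L, fp = 0L, fn = 5L))
    expect_error(confusionCounts(yt, yt[-1L]), "length")
})

test_that("confusion counts match a brute-force pairwise oracle", {
    set.seed(77)
    for (i in 1:20) {
        n <- sample(5:60, 1L)
        yt <- sample(c("seizure", "normal"), n, replace = TRUE)
        yp <- sample(c("seizure", "normal"), n, replace = TRUE)
        got <- countValues(confusionCounts(yt, yp))
        oracle <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
        for (j in seq_len(n)) {
            key <- if (yt[j] == "seizure" && yp[j] == "seizure") "tp"
                   else if (yt[j] == "normal" && yp[j] == "normal") "tn"
                   else if (yt[j] == "normal") "fp" else "fn"
            oracle[key] <- oracle[key] + 1L
        }
        expect_equal(got, oracle)
    }
})

test_that("the nine metrics reproduce published worked examples", {
    m1 <- metricValues(computeMetrics(confusionCountsFromValues(37, 31, 6, 6)))
    expect_equal(m1[["accuracy"]], 85)
    expect_equal(m1[["sensitivity"]], 86.04651, tolerance = 1e-7)
    expect_equal(m1[["specificity"]], 83.78378, tolerance = 1e-7)
    expect_equal(m1[["missRate"]], 13.95349, tolerance = 1e-6)

    m2 <- metricValues(computeMetrics(confusionCountsFromValues(42, 31, 9, 0)))
    expect_equal(m2[["accuracy"]], 89.02439, tolerance = 1e-7)
    expect_equal(m2[["sensitivity"]], 100)
    expect_equal(m2[["positivePredictivity"]], 82.35294, tolerance = 1e-7)
    expect_equal(m2[["f1"]], 90.32258, tolerance = 1e-7)

    m3 <- metricValues(computeMetrics(confusionCountsFromValues(1, 1, 0, 0)))
    expect_equal(unname(m3[c("accuracy", "sensitivity", "specificity",
                             "precision", "recall", "f1",
                             "positivePredictivity")]), rep(100, 7))
    expect_equal(unname(m3[c("fallOut", "missRate")]), c(0, 0))
})

test_that("metric identities hold for arbitrary valid counts", {
    set.seed(55)
    for (i in 1:30) {
        cc <- confusionCountsFromValues(sample(1:50, 1L), sample(1:50, 1L),
                                        sample(0:50, 1L), sample(0:50, 1L))
        m <- metricValues(computeMetrics(cc))
        expect_equal(m[["sensitivity"]] + m[["missRate"]], 100)
        expect_equal(m[["specificity"]] + m[["fallOut"]], 100)
        expect_equal(m[["sensitivity"]], m[["recall"]])
        expect_equal(m[["positivePredictivity"]], m[["precision"]])
        expect_gte(m[["f1"]], min(m[["precision"]], m[["recall"]]) - 1e-9)
        expect_lte(m[["f1"]], max(m[["precision"]], m[["recall"]]) + 1e-9)
    }
})

test_that("zero denominators give NA with a warning, never silent zeros", {
    expect_warning(
        expect_warning(
            m <- computeMetrics(confusionCountsFromValues(0, 5, 0, 0)),
            "sensitivity undefined"),
        "positive predictivity undefined")
    expect_true(is.na(metricValues(m)[["sensitivity"]]))
    expect_true(is.na(metricValues(m)[["missRate"]]))
    expect_equal(metricValues(m)[["specificity"]], 100)
})

test_that("k-fold assignment is a stratified, balanced, seeded partition", {
    state <- rep(c("seizure", "normal"), c(23L, 31L))
    ft <- simulateFeatureTable(27L, effect = 1, seed = 1L)
    for (K in c(2L, 5L, 7L)) {
        f <- kfoldAssign(state, K = K, seed = 3L)
        ## partition: every row in exactly one fold
        expect_equal(sort(unique(f)), seq_len(K))
        expect_equal(length(f), length(state))
        sizes <- tabulate(f, K)
        expect_lte(diff(range(sizes)), 1L)
        for (cls in c("seizure", "normal"))
            expect_lte(diff(range(tabulate(f[state == cls], K))), 1L)
    }
    expect_identical(kfoldAssign(state, 5L, seed = 9L),
                     kfoldAssign(state, 5L, seed = 9L))
    expect_error(kfoldAssign(rep(c("seizure", "normal"), c(3L, 50L)), 5L),
                 "fewer than K")
    ## K = n gives leave-one-out: every fold is a single row
    loo <- kfoldAssign(rep(c("seizure", "normal"), each = 4L), K = 8L,
                       seed = 1L)
    expect_equal(sort(loo), 1:8)
})

test_that("250 rows split 5-fold into five folds of 50", {
    state <- rep(c("seizure", "normal"), each = 125L)
    f <- kfoldAssign(state, K = 5L, seed = 2L)
    expect_equal(unname(tabulate(f, 5L)), rep(50L, 5L))
})

test_that("cross-validation pools exactly the per-fold confusions", {
    ft <- simulateFeatureTable(20L, effect = 2, seed = 12L)
    cv <- crossValidate("knn", ft, K = 5L, seed = 3L)
    perFoldSum <- Reduce(`+`, lapply(cv@perFold, function(r)
        countValues(r@counts)))
    expect_equal(perFoldSum, countValues(cv@pooled@counts))
    expect_equal(sum(countValues(cv@pooled@counts)), nrow(ft))
    ## a separable table cross-validates perfectly
    cvSep <- crossValidate("lda", separableTable(10L), K = 5L, seed = 1L)
    expect_equal(metricValues(cvSep@pooled)[["accuracy"]], 100)
})

test_that("the abnormal-sample filter removes planted noise rows only", {
    ft <- simulateFeatureTable(20L, effect = 3, seed = 15L)
    ## plant a normal row deep inside the seizure cluster on the Mean feature
    sMean <- median(featureMatrix(ft)[stateLabels(ft) == "seizure", "Mean"])
    nMean <- median(featureMatrix(ft)[stateLabels(ft) == "normal", "Mean"])
    nMad <- mad(featureMatrix(ft)[stateLabels(ft) == "normal", "Mean"])
    planted <- ft
    dir <- sign(sMean - nMean); if (dir == 0) dir <- 1
    idx <- which(stateLabels(planted) == "normal")[1L]
    planted@features$Mean[idx] <- nMean + dir * 10 * nMad
    res <- filterAbnormal(planted, zThreshold = 3)
    expect_true(idx %in% res$removed$row)
    expect_equal(nrow(res$table), nrow(planted) - nrow(res$removed))
})

test_that("clean synthetic tables survive the z = 3 filter in most seeded runs", {
    ## at the pipeline's training scale (250 rows) the robust scale estimate
    ## is stable enough that a clean table should essentially never lose rows
    clean <- 0L
    for (s in 1:20) {
        ft <- simulateFeatureTable(125L, effect = 3, seed = 100L + s)
        if (nrow(filterAbnormal(ft, 3)$removed) == 0L) clean <- clean + 1L
    }
    expect_gte(clean / 20, 0.95)
})

test_that("filtering contaminated training tables improves CV accuracy on average", {
    deltas <- vapply(1:5, function(s) {
        ft <- simulateFeatureTable(30L, effect = 3, seed = 200L + s)
        ## contaminate: four seizure-like feature rows mislabelled normal,
        ## pushed far out on the designated observation feature
        nMean <- median(featureMatrix(ft)[stateLabels(ft) == "normal", "Mean"])
        nMad <- mad(featureMatrix(ft)[stateLabels(ft) == "normal", "Mean"])
        sRows <- which(stateLabels(ft) == "seizure")[1:4]
        bad <- which(stateLabels(ft) == "normal")[1:4]
        ft@features[bad, ] <- ft@features[sRows, ]
        ft@features$Mean[bad] <- nMean + 10 * nMad
        accRaw <- metricValues(crossValidate("knn", ft, 5L,
                                             seed = s)@pooled)[["accuracy"]]
        accFilt <- metricValues(crossValidate(
            "knn", filterAbnormal(ft, 3)$table, 5L,
            seed = s)@pooled)[["accuracy"]]
        accFilt - accRaw
    }, numeric(1L))
    expect_gt(mean(deltas), 0)
})

test_that("metric JSON and the evaluation text table are well formed", {
    cv <- crossValidate("lda", separableTable(10L), K = 5L, seed = 1L)
    f <- withr::local_tempfile(fileext = ".json")
    writeMetricsJSON(cv, f, config = list(seed = 1L, K = 5L))
    parsed <- jsonlite::read_json(f)
    expect_equal(parsed$pooled$metrics$accuracy, 100)
    expect_equal(parsed$config$seed, 1L)
    expect_length(parsed$perFold, 5L)

    lines <- formatMetricsTable(list(
        knn = computeMetrics(confusionCountsFromValues(37, 31, 6, 6))))
    expect_match(lines[1L], "Metric\\s+knn")
    expect_match(lines[grep("MisRate", lines)], "13.95349")
})
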