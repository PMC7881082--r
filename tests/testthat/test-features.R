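test_that("a constant signal degenerates as specified", {
    expect_warning(fv <- extractFeatures(rep(7, 16)), "zero-variance")
    expect_equal(fv[["STD"]], 0)
    expect_equal(fv[["Var"]], 0)
    expect_equal(fv[["Mean"]], 7)
    expect_equal(fv[["Med"]], 7)
    expect_equal(fv[["Max"]], 7)
    expect_equal(fv[["Min"]], 7)
    expect_equal(fv[["SKW"]], 0)
    expect_equal(fv[["KRT"]], 0)
    expect_equal(fv[["POW"]], 16^2 * 7^2)   # N^2 c^2
    expect_error(extractFeatures(c(1, 2, 3)), "at least 4 samples")
})

test_that("Parseval and moment identities hold on random signals", {
    set.seed(123)
    for (i in 1:50) {
        n <- sample(16:512, 1L)
        x <- rnorm(n, sd = runif(1, 0.1, 100)) + runif(1, -50, 50)
        fv <- extractFeatures(x)
        expect_equal(fv[["POW"]], n * sum(x^2), tolerance = 1e-9)
        sigmaPop2 <- mean((x - mean(x))^2)
        expect_equal(fv[["MOM"]], fv[["KRT"]] * sigmaPop2^2,
                     tolerance = 1e-9)
        expect_equal(fv[["Var"]], fv[["STD"]]^2, tolerance = 1e-12)
        expect_lte(fv[["Min"]], fv[["Med"]])
        expect_lte(fv[["Med"]], fv[["Max"]])
    }
})

test_that("kurtosis is non-excess and skewness is the third standardised moment", {
    set.seed(2024)
    x <- rnorm(1e5)
    fv <- extractFeatures(x)
    expect_equal(fv[["KRT"]], 3, tolerance = 0.1 / 3)   # Gaussian -> 3
    expect_lt(abs(fv[["SKW"]]), 0.1)
    ## right-skewed sample has positive SKW (would be ~3 if it duplicated KRT)
    y <- rexp(1e5)
    fy <- extractFeatures(y)
    expect_equal(fy[["SKW"]], 2, tolerance = 0.1)
    expect_equal(fy[["KRT"]], 9, tolerance = 0.2)
})

test_that("affine shifts move location features and leave shape features alone", {
    set.seed(5)
    x <- rnorm(256, sd = 10)
    a <- extractFeatures(x)
    b <- extractFeatures(x + 42)
    for (nm in c("Mean", "Med", "Max", "Min"))
        expect_equal(b[[nm]], a[[nm]] + 42, tolerance = 1e-9)
    for (nm in c("STD", "Var", "SKW", "KRT", "MOM"))
        expect_equal(b[[nm]], a[[nm]], tolerance = 1e-9)
})

test_that("moment order is configurable and defaults to 4", {
    set.seed(8)
    x <- rnorm(128)
    expect_equal(extractFeatures(x)[["MOM"]], mean((x - mean(x))^4))
    expect_equal(extractFeatures(x, momentOrder = 2L)[["MOM"]],
                 mean((x - mean(x))^2))
})

test_that("entropy responds to histogram configuration and spread", {
    set.seed(9)
    x <- rnorm(4096)
    eNat <- extractFeatures(x)[["ENT"]]
    e2 <- extractFeatures(x, entropyBase = 2)[["ENT"]]
    expect_equal(e2, eNat / log(2), tolerance = 1e-9)
    eCoarse <- extractFeatures(x, entropyBins = 10L)[["ENT"]]
    expect_lt(eCoarse, eNat)      # fewer bins, less histogram entropy
    expect_lte(eNat, log(100))    # bounded by log(bins)
})

test_that("averaging the worked channel rows reproduces the averaged row", {
    m <- workedChannelFeatures()
    avg <- averageFeatures(m)
    expect_equal(round(avg[["STD"]], 2), 415.71)
    expect_equal(round(avg[["Mean"]], 2), 5.23)
    expect_equal(round(avg[["Max"]], 2), 1105.00)
    expect_equal(round(avg[["Min"]], 2), -1324.33)
    expect_equal(round(avg[["Med"]], 2), 11.33)
    expect_equal(round(avg[["SKW"]], 2), -0.08)
    expect_equal(round(avg[["ENT"]], 2), 4.67)
    expect_equal(round(avg[["KRT"]], 2), 2.79)
    ## inputs carry 3 significant digits; tolerate that rounding
    expect_equal(avg[["Var"]], 1.74e5, tolerance = 0.005)
    expect_equal(avg[["MOM"]], 8.34e10, tolerance = 0.005)
    expect_equal(avg[["POW"]], 1.14e12, tolerance = 0.005)
})

test_that("averaging is an identity for one vector and permutation-invariant", {
    set.seed(3)
    v1 <- extractFeatures(rnorm(64))
    v2 <- extractFeatures(rnorm(64, sd = 5))
    v3 <- extractFeatures(runif(64))
    expect_equal(averageFeatures(list(v1)), v1)
    expect_equal(averageFeatures(list(v1, v2, v3)),
                 averageFeatures(list(v3, v1, v2)))
    expect_error(averageFeatures(list()), "at least one")
})

test_that("buildFeatureTable averages the top-k channels per window", {
    cfg <- synthConfig(nChannels = 4L, fs = 32, durationS = 120,
                       seizureIntervals = cbind(c(20, 80), c(50, 110)),
                       burstChannels = c(1L, 3L), seed = 21L)
    windows <- windowContinuous(simulateRecord(cfg), 10)
    ft <- buildFeatureTable(windows, k = 3L)
    expect_s4_class(ft, "FeatureTable")
    expect_equal(nrow(ft), length(windows))
    expect_identical(colnames(featureMatrix(ft)),
                     c("STD", "Mean", "Max", "Min", "Var", "Med",
                       "SKW", "ENT", "KRT", "MOM", "POW"))
    ## k = 1: the row is exactly the top-variance channel's features
    ft1 <- buildFeatureTable(windows[1L], k = 1L)
    w <- windows[[1L]]
    top <- selectedChannels(selectTopK(channelVariance(w), 1L))
    expect_equal(unname(featureMatrix(ft1)[1L, ]),
                 unname(extractFeatures(eegSignal(w)[top, ])))
    expect_identical(stateLabels(ft1), windowLabel(w))
})

test_that("feature tables round-trip through the CSV layout", {
    ft <- simulateFeatureTable(5L, effect = 2, seed = 4L)
    f <- withr::local_tempfile(fileext = ".csv")
    writeFeatureTable(ft, f, comment = "seed=4")
    ## State codes on disk are s/n in the canonical column order
    hdr <- strsplit(readLines(f, n = 2L)[2L], ",")[[1L]]
    expect_identical(hdr[1:12],
                     c("STD", "Mean", "Max", "Min", "Var", "Med", "SKW",
                       "ENT", "KRT", "MOM", "POW", "State"))
    back <- readFeatureTable(f)
    expect_equal(featureMatrix(back), featureMatrix(ft), tolerance = 1e-9)
    expect_identical(stateLabels(back), stateLabels(ft))
})
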