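## Shared fixtures, all built in code at test time.

## Deterministic record: per-channel sinusoids + linear trend, optional
## annotations. Cheap and exactly reproducible without RNG.
makeRecord <- function(nChannels = 3L, fs = 8, durationS = 100,
                       annotations = NULL, recordId = "fix") {
    n <- as.integer(round(fs * durationS))
    tt <- (seq_len(n) - 1L) / fs
    sig <- t(vapply(seq_len(nChannels), function(ch)
        sin(2 * pi * (0.5 + 0.1 * ch) * tt) * (10 * ch) + 0.01 * ch * tt,
        numeric(n)))
    eegRecord(sig, fs = fs, annotations = annotations, recordId = recordId)
}

## A window whose per-channel population variances are exactly `variances`:
## channel c alternates +/- sqrt(V_c), so mean 0 and popvar V_c.
windowWithVariances <- function(variances, nSamplesPerChannel = 8L,
                                label = "seizure") {
    stopifnot(nSamplesPerChannel %% 2L == 0L)
    sig <- t(vapply(variances, function(v)
        rep(c(sqrt(v), -sqrt(v)), nSamplesPerChannel / 2L),
        numeric(nSamplesPerChannel)))
    new("EEGWindow", signal = sig, label = label, recordId = "var-fix",
        startS = 0, fs = 1)
}

## Linearly separable toy feature table: the amplitude family (STD, Var,
## Max, Min, MOM, POW) separates the classes with a wide margin; the five
## remaining columns are class-independent noise.
separableTable <- function(nPerClass = 12L, seed = 99L) {
    n <- 2L * nPerClass
    set.seed(seed)
    cls <- rep(c("seizure", "normal"), each = nPerClass)
    std <- ifelse(cls == "seizure", runif(n, 400, 500), runif(n, 50, 100))
    featureTable(
        data.frame(STD = std, Mean = rnorm(n, 0, 5),
                   Max = std * runif(n, 2.8, 3.4),
                   Min = -std * runif(n, 2.8, 3.4),
                   Var = std^2, Med = rnorm(n, 0, 10),
                   SKW = rnorm(n, 0, 0.2), ENT = rnorm(n, 4.5, 0.2),
                   KRT = rnorm(n, 3, 0.3),
                   MOM = 3 * std^4 * runif(n, 0.9, 1.1),
                   POW = 2560^2 * std^2 * runif(n, 0.9, 1.1)),
        state = cls)
}

## Worked-example per-channel variances (23 channels) and the three
## selected-channel feature rows, shipped as plain-text package data.
workedVariances <- function() {
    df <- read.csv(system.file("extdata", "worked_example_variances.csv",
                               package = "ictalEEG"))
    stats::setNames(df$variance, df$channel)
}

workedChannelFeatures <- function() {
    df <- read.csv(system.file("extdata", "worked_example_channel_features.csv",
                               package = "ictalEEG"))
    m <- as.matrix(df[, -1L])
    rownames(m) <- df$channel
    m
}
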