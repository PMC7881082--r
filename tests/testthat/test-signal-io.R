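test_that("EDF round trip preserves shape, rate and values within quantisation", {
    rec <- makeRecord(nChannels = 2L, fs = 16, durationS = 8, recordId = "rt")
    f <- withr::local_tempfile(fileext = ".edf")
    scale <- writeEDF(rec, f)
    back <- readEDF(f)
    expect_equal(nChannels(back), 2L)
    expect_equal(samplingRate(back), 16)
    expect_equal(nSamples(back), nSamples(rec))
    ## 16-bit storage: exact up to half a quantisation step per channel
    for (ch in 1:2)
        expect_lt(max(abs(eegSignal(back)[ch, ] - eegSignal(rec)[ch, ])),
                  scale[ch] / 2 + 1e-12)
})

test_that("a 23-channel 256 Hz 60-s EDF reads back with 15360 samples", {
    rec <- simulateRecord(synthConfig(nChannels = 23L, fs = 256,
                                      durationS = 60,
                                      seizureIntervals = cbind(10, 30),
                                      seed = 5L))
    f <- withr::local_tempfile(fileext = ".edf")
    writeEDF(rec, f)
    back <- readEDF(f)
    expect_equal(nSamples(back), 60L * 256L)   # oracle: 60 x 256
    expect_equal(samplingRate(back), 256)
    expect_equal(nChannels(back), 23L)
})

test_that("corrupt EDF headers fail with the offending field named", {
    f <- withr::local_tempfile(fileext = ".edf")
    rec <- makeRecord(nChannels = 2L, fs = 8, durationS = 4)
    writeEDF(rec, f)
    raw <- readBin(f, "raw", file.size(f))

    ## zero signals declared
    bad <- raw
    bad[253:256] <- charToRaw("0   ")
    f0 <- withr::local_tempfile(fileext = ".edf")
    writeBin(bad, f0)
    expect_error(readEDF(f0), "number of signals")

    ## truncated mid-header
    fTrunc <- withr::local_tempfile(fileext = ".edf")
    writeBin(raw[1:200], fTrunc)
    expect_error(readEDF(fTrunc), "truncated.*header")

    ## non-numeric record count
    bad2 <- raw
    bad2[237:244] <- charToRaw("oops    ")
    f2 <- withr::local_tempfile(fileext = ".edf")
    writeBin(bad2, f2)
    expect_error(readEDF(f2), "number of data records")
})

test_that("EDF signals with differing sampling rates are rejected", {
    rec <- makeRecord(nChannels = 2L, fs = 8, durationS = 4)
    f <- withr::local_tempfile(fileext = ".edf")
    writeEDF(rec, f)
    raw <- readBin(f, "raw", file.size(f))
    ## per-signal 'samples per record' fields sit after 7 field blocks
    off <- 256L + 2L * (16L + 80L + 8L + 8L + 8L + 8L + 8L + 80L)
    raw[(off + 9L):(off + 16L)] <- charToRaw("4       ")
    f2 <- withr::local_tempfile(fileext = ".edf")
    writeBin(raw, f2)
    expect_error(readEDF(f2), "differing sampling rates")
})

test_that("EDF written here is readable by an independent EDF implementation", {
    rec <- makeRecord(nChannels = 3L, fs = 32, durationS = 6, recordId = "x")
    f <- withr::local_tempfile(fileext = ".edf")
    writeEDF(rec, f)
    out <- withr::local_tempfile(fileext = ".csv")
    code <- sprintf(paste0(
        "import mne, numpy as np\n",
        "raw = mne.io.read_raw_edf(r'%s', preload=True, verbose='ERROR')\n",
        "d = raw.get_data()\n",
        "np.savetxt(r'%s', d, delimiter=',')\n",
        "print(raw.info['sfreq'])\n"), f, out)
    res <- system2("python", c("-c", shQuote(code)), stdout = TRUE,
                   stderr = FALSE)
    expect_equal(as.numeric(res[length(res)]), 32)
    got <- as.matrix(read.csv(out, header = FALSE))
    ## mne scales EDF 'uV' channels to volts
    expect_equal(unname(got) * 1e6, unname(eegSignal(rec)),
                 tolerance = 1e-3)
})

test_that("CSV record round trip is the identity on values", {
    rec <- makeRecord(nChannels = 3L, fs = 10, durationS = 5, recordId = "csv")
    f <- withr::local_tempfile(fileext = ".csv")
    writeCSVRecord(rec, f, comment = "config: test")
    back <- readCSVRecord(f, fs = 10)
    expect_equal(eegSignal(back), eegSignal(rec), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_identical(channelLabels(back), channelLabels(rec))
})

test_that("CSV record dialect is channel-major with fs as given", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("A,B,C", paste(1:10, 11:20, 21:30, sep = ",")), f)
    rec <- readCSVRecord(f, fs = 1)
    expect_equal(nChannels(rec), 3L)
    expect_equal(nSamples(rec), 10L)
    expect_equal(samplingRate(rec), 1)
    expect_equal(eegSignal(rec)[2L, ], as.numeric(11:20), ignore_attr = TRUE)
})

test_that("malformed CSV records fail with informative errors", {
    fEmpty <- withr::local_tempfile(fileext = ".csv")
    writeLines("A,B,C", fEmpty)
    expect_error(readCSVRecord(fEmpty, fs = 1), "no data rows")

    fBad <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("A,B", "1,2", "3,x", "5,6"), fBad)
    expect_error(readCSVRecord(fBad, fs = 1), "row 2")

    fRagged <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("A,B", "1,2", "3,4,5"), fRagged)
    expect_error(readCSVRecord(fRagged, fs = 1), "format error")
})

test_that("annotation sidecar round-trips and filters by record id", {
    ann <- data.frame(start_s = c(10, 50), end_s = c(20, 80))
    rec <- makeRecord(fs = 4, durationS = 100, annotations = ann,
                      recordId = "recA")
    f <- withr::local_tempfile(fileext = ".csv")
    writeAnnotations(rec, f)
    expect_equal(readAnnotations(f, recordId = "recA"), ann,
                 ignore_attr = TRUE)
    expect_equal(nrow(readAnnotations(f, recordId = "other")), 0L)
})
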