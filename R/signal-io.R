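## EDF (European Data Format) reader/writer.
##
## EDF is a fixed-layout 16-bit format: a 256-byte ASCII global header, one
## 256-byte ASCII header block per signal (field-major), then data records of
## little-endian int16 samples, signal by signal. Physical values are
## recovered by the per-signal linear digital->physical map; round trips are
## therefore exact up to one digital quantisation step (half the stored
## scale factor).

.edfPad <- function(s, width) {
    s <- as.character(s)
    if (nchar(s) > width) s <- substr(s, 1L, width)
    formatC(s, width = -width)
}

## Format a number into at most `width` ASCII chars, reducing precision as
## needed (EDF numeric header fields are 8 chars).
.edfNum <- function(x, width = 8L) {
    for (d in seq(10L, 1L)) {
        s <- formatC(x, format = "g", digits = d, width = 0L)
        if (nchar(s) <= width) return(.edfPad(s, width))
    }
    .stopf("cannot represent %g in a %d-char EDF header field", x, width)
}

#' Write an EEG record to an EDF file
#'
#' Stores the signal as standard 16-bit EDF. The physical range of each
#' channel is mapped onto the full digital range, so values are preserved to
#' within half a quantisation step (range / 65535). Annotations are not part
#' of plain EDF; write them with [writeAnnotations()].
#'
#' @param record an [EEGRecord-class]. The sampling rate must be a positive
#'   integer unless the whole record is written as one data record.
#' @param path output file path.
#' @return invisibly, the per-channel quantisation step (microvolts).
#' @seealso [readEDF()]
#' @export
writeEDF <- function(record, path) {
    stopifnot(is(record, "EEGRecord"))
    sig <- record@signal
    ns <- nrow(sig)
    n <- ncol(sig)
    fs <- record@fs
    if (abs(fs - round(fs)) < 1e-9 && n %% round(fs) == 0L) {
        spr <- as.integer(round(fs))     # one-second data records
        nrec <- n %/% spr
        recdur <- 1
    } else {
        spr <- n                         # single data record
        nrec <- 1L
        recdur <- n / fs
    }
    physMin <- apply(sig, 1L, min)
    physMax <- apply(sig, 1L, max)
    flat <- physMax - physMin <= 0
    physMin[flat] <- physMin[flat] - 1
    physMax[flat] <- physMax[flat] + 1
    digMin <- -32768L
    digMax <- 32767L

    con <- file(path, "wb")
    on.exit(close(con))
    wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
    wr(.edfPad("0", 8L))                       # version
    wr(.edfPad(record@recordId, 80L))          # patient id field
    wr(.edfPad("ictalEEG export", 80L))        # recording id field
    wr(.edfPad("01.01.26", 8L))
    wr(.edfPad("00.00.00", 8L))
    wr(.edfNum(256L * (ns + 1L), 8L))          # header bytes
    wr(.edfPad("", 44L))
    wr(.edfNum(nrec, 8L))
    wr(.edfNum(recdur, 8L))
    wr(.edfNum(ns, 4L))
    for (lab in record@channelLabels) wr(.edfPad(lab, 16L))
    for (i in seq_len(ns)) wr(.edfPad("", 80L))        # transducer
    for (i in seq_len(ns)) wr(.edfPad("uV", 8L))       # physical dimension
    for (i in seq_len(ns)) wr(.edfNum(physMin[i], 8L))
    for (i in seq_len(ns)) wr(.edfNum(physMax[i], 8L))
    for (i in seq_len(ns)) wr(.edfNum(digMin, 8L))
    for (i in seq_len(ns)) wr(.edfNum(digMax, 8L))
    for (i in seq_len(ns)) wr(.edfPad("", 80L))        # prefiltering
    for (i in seq_len(ns)) wr(.edfNum(spr, 8L))
    for (i in seq_len(ns)) wr(.edfPad("", 32L))

    ## reparse the (possibly precision-reduced) header fields so the stored
    ## linear map is used for encoding, making read(write(x)) self-consistent
    pMin <- vapply(physMin, function(v) as.numeric(.edfNum(v, 8L)), numeric(1L))
    pMax <- vapply(physMax, function(v) as.numeric(.edfNum(v, 8L)), numeric(1L))
    scale <- (pMax - pMin) / (digMax - digMin)
    for (r in seq_len(nrec)) {
        cols <- ((r - 1L) * spr + 1L):(r * spr)
        for (i in seq_len(ns)) {
            dig <- as.integer(round((sig[i, cols] - pMin[i]) / scale[i]) + digMin)
            dig <- pmin(pmax(dig, digMin), digMax)
            writeBin(dig, con, size = 2L, endian = "little")
        }
    }
    invisible(scale)
}

.edfReadField <- function(con, width, name, numeric = FALSE) {
    raw <- readChar(con, width, useBytes = TRUE)
    if (length(raw) == 0L || nchar(raw, type = "bytes") < width)
        .stopf("EDF format error: truncated file while reading header field '%s'",
               name)
    val <- trimws(raw)
    if (numeric) {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num))
            .stopf("EDF format error: header field '%s' is not numeric ('%s')",
                   name, val)
        return(num)
    }
    val
}

#' Read an EDF file into an EEG record
#'
#' Reads a plain (non-EDF+) 16-bit EDF file. All signals must share one
#' sampling rate. Seizure annotations are attached from the optional sidecar
#' annotation CSV (see [readAnnotations()]); without one the record has no
#' annotations.
#'
#' @param path path to the EDF file.
#' @param annotationsPath optional path to a sidecar annotation CSV with
#'   columns \code{record_id,start_s,end_s}.
#' @param recordId record identifier; defaults to the file name without
#'   extension. Used to pick this record's rows from the sidecar file.
#' @return an [EEGRecord-class].
#' @examples
#' rec <- simulateRecord(synthConfig(nChannels = 2, fs = 32, durationS = 4,
#'                                   seizureIntervals = NULL, seed = 7))
#' f <- tempfile(fileext = ".edf")
#' writeEDF(rec, f)
#' readEDF(f)
#' @export
readEDF <- function(path, annotationsPath = NULL, recordId = NULL) {
    if (!file.exists(path)) .stopf("EDF file not found: %s", path)
    con <- file(path, "rb")
    on.exit(close(con))
    .edfReadField(con, 8L, "version")
    patient <- .edfReadField(con, 80L, "patient")
    .edfReadField(con, 80L, "recording")
    .edfReadField(con, 8L, "startdate")
    .edfReadField(con, 8L, "starttime")
    hdrBytes <- .edfReadField(con, 8L, "header bytes", numeric = TRUE)
    .edfReadField(con, 44L, "reserved")
    nrec <- .edfReadField(con, 8L, "number of data records", numeric = TRUE)
    recdur <- .edfReadField(con, 8L, "record duration", numeric = TRUE)
    ns <- .edfReadField(con, 4L, "number of signals", numeric = TRUE)
    if (ns < 1)
        .stopf("EDF format error: header field 'number of signals' is %g (need >= 1)", ns)
    if (recdur <= 0)
        .stopf("EDF format error: header field 'record duration' must be positive")
    if (hdrBytes != 256 * (ns + 1))
        .stopf("EDF format error: header field 'header bytes' (%g) does not match %g signals",
               hdrBytes, ns)
    ns <- as.integer(ns)
    labels <- vapply(seq_len(ns), function(i)
        .edfReadField(con, 16L, "signal label"), character(1L))
    for (i in seq_len(ns)) .edfReadField(con, 80L, "transducer")
    for (i in seq_len(ns)) .edfReadField(con, 8L, "physical dimension")
    physMin <- vapply(seq_len(ns), function(i)
        .edfReadField(con, 8L, "physical minimum", TRUE), numeric(1L))
    physMax <- vapply(seq_len(ns), function(i)
        .edfReadField(con, 8L, "physical maximum", TRUE), numeric(1L))
    digMin <- vapply(seq_len(ns), function(i)
        .edfReadField(con, 8L, "digital minimum", TRUE), numeric(1L))
    digMax <- vapply(seq_len(ns), function(i)
        .edfReadField(con, 8L, "digital maximum", TRUE), numeric(1L))
    for (i in seq_len(ns)) .edfReadField(con, 80L, "prefiltering")
    spr <- vapply(seq_len(ns), function(i)
        .edfReadField(con, 8L, "samples per record", TRUE), numeric(1L))
    for (i in seq_len(ns)) .edfReadField(con, 32L, "reserved (signal)")
    if (any(digMax <= digMin))
        .stopf("EDF format error: header field 'digital maximum' must exceed 'digital minimum'")
    if (length(unique(spr)) != 1L)
        .stopf("unsupported EDF: signals have differing sampling rates (samples per record: %s)",
               paste(unique(spr), collapse = ", "))
    spr <- as.integer(spr[1L])
    fs <- spr / recdur
    if (nrec < 0) {                       # -1 means 'unknown': infer from size
        avail <- file.size(path) - 256L * (ns + 1L)
        nrec <- avail %/% (2L * spr * ns)
    }
    nrec <- as.integer(nrec)
    scale <- (physMax - physMin) / (digMax - digMin)
    sig <- matrix(0, nrow = ns, ncol = nrec * spr)
    for (r in seq_len(nrec)) {
        cols <- ((r - 1L) * spr + 1L):(r * spr)
        for (i in seq_len(ns)) {
            dig <- readBin(con, "integer", n = spr, size = 2L, signed = TRUE,
                           endian = "little")
            if (length(dig) < spr)
                .stopf("EDF format error: truncated data record %d", r)
            sig[i, cols] <- (dig - digMin[i]) * scale[i] + physMin[i]
        }
    }
    if (is.null(recordId))
        recordId <- if (nzchar(patient)) patient
                    else sub("\\.[^.]*$", "", basename(path))
    ann <- NULL
    if (!is.null(annotationsPath))
        ann <- readAnnotations(annotationsPath, recordId = recordId)
    eegRecord(sig, fs = fs, channelLabels = make.unique(labels),
              annotations = ann, recordId = recordId)
}

#' Read and write seizure annotations
#'
#' Annotations travel in a sidecar CSV with columns
#' \code{record_id,start_s,end_s}; intervals are half-open
#' \code{[start_s, end_s)} in seconds from record start.
#'
#' @param path CSV file path.
#' @param recordId if given, only rows with this \code{record_id} are
#'   returned (as a bare \code{start_s}/\code{end_s} data.frame).
#' @return \code{readAnnotations}: a data.frame.
#' @export
readAnnotations <- function(path, recordId = NULL) {
    df <- utils::read.csv(path, comment.char = "#",
                          colClasses = c(record_id = "character"))
    need <- c("record_id", "start_s", "end_s")
    if (!all(need %in% names(df)))
        .stopf("annotation file %s must have columns %s", path,
               paste(need, collapse = ","))
    if (!is.null(recordId))
        df <- df[df$record_id == recordId, c("start_s", "end_s"), drop = FALSE]
    df
}

#' @rdname readAnnotations
#' @param record an [EEGRecord-class] whose annotations are written.
#' @export
writeAnnotations <- function(record, path) {
    ann <- record@annotations
    df <- data.frame(record_id = rep(record@recordId, nrow(ann)),
                     start_s = ann$start_s, end_s = ann$end_s)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Read an EEG record from the CSV signal dialect
#'
#' The CSV dialect stores one column per channel (header row = channel
#' labels) and one row per time sample; lines starting with \code{#} carry
#' embedded metadata and are skipped. The matrix is transposed into
#' channel-major order on read.
#'
#' @param path CSV file path.
#' @param fs sampling rate in Hz (not stored in the CSV).
#' @param annotationsPath optional sidecar annotation CSV.
#' @param recordId record identifier; defaults to the file name.
#' @return an [EEGRecord-class].
#' @seealso [writeCSVRecord()]
#' @export
readCSVRecord <- function(path, fs, annotationsPath = NULL, recordId = NULL) {
    if (!file.exists(path)) .stopf("CSV record not found: %s", path)
    df <- tryCatch(
        utils::read.table(path, header = TRUE, sep = ",",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "#"),
        error = function(e) .stopf("CSV record format error in %s: %s",
                                   path, conditionMessage(e)))
    if (nrow(df) == 0L)
        .stopf("CSV record format error in %s: no data rows below the header",
               path)
    num <- vapply(df, function(col) suppressWarnings(as.numeric(col)),
                  numeric(nrow(df)))
    num <- matrix(num, nrow = nrow(df))
    if (anyNA(num)) {
        bad <- which(apply(num, 1L, anyNA))[1L]
        .stopf("CSV record format error in %s: non-numeric cell in data row %d",
               path, bad)
    }
    if (is.null(recordId)) recordId <- sub("\\.[^.]*$", "", basename(path))
    ann <- if (!is.null(annotationsPath))
        readAnnotations(annotationsPath, recordId = recordId) else NULL
    eegRecord(t(num), fs = fs, channelLabels = names(df),
              annotations = ann, recordId = recordId)
}

#' Write an EEG record to the CSV signal dialect
#'
#' @param record an [EEGRecord-class].
#' @param path output path.
#' @param comment optional character vector of metadata lines to embed as
#'   leading \code{#} comments (e.g. a resolved run configuration).
#' @seealso [readCSVRecord()]
#' @export
writeCSVRecord <- function(record, path, comment = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(comment))
        writeLines(paste0("# ", comment), con)
    df <- as.data.frame(t(record@signal))
    names(df) <- record@channelLabels
    utils::write.csv(format(df, trim = TRUE, digits = 15), con,
                     row.names = FALSE, quote = FALSE)
    invisible(path)
}
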