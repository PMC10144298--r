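## Minimal reader for 16-bit EDF (European Data Format) as used by the
## CHB-MIT scalp EEG corpus: ASCII header, per-signal subheaders, data
## records of little-endian int16 samples scaled to physical units.

#' EEGRecording: a multi-channel EEG recording
#'
#' @slot channels channel labels in acquisition order (duplicated labels are
#'   disambiguated by their acquisition index, e.g. \code{"T8P8#2"}).
#' @slot data samples-by-channels numeric matrix in physical units.
#' @slot fs sampling rate in Hz (uniform across channels).
#' @slot annotations data.frame of seizure intervals with columns
#'   \code{start_s}, \code{end_s} (possibly zero rows).
#' @name EEGRecording-class
#' @exportClass EEGRecording
setClass("EEGRecording",
    representation(channels = "character", data = "matrix", fs = "numeric",
                   annotations = "data.frame"))

setValidity("EEGRecording", function(object) {
    msg <- NULL
    if (ncol(object@data) != length(object@channels))
        msg <- c(msg, "one data column per channel required")
    if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
    ann <- object@annotations
    if (nrow(ann)) {
        dur <- nrow(object@data) / object@fs
        if (any(ann$start_s >= ann$end_s))
            msg <- c(msg, "annotation intervals must have start < end")
        if (any(ann$start_s < 0) || any(ann$end_s > dur + 1e-9))
            msg <- c(msg, "annotation intervals must lie within the record")
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "EEGRecording", function(object) {
    cat("EEGRecording:", length(object@channels), "channels x",
        nrow(object@data), "samples @", object@fs, "Hz (",
        round(nrow(object@data) / object@fs, 1), "s );",
        nrow(object@annotations), "seizure interval(s)\n")
})

.edfField <- function(raw, offset, width) {
    trimws(rawToChar(raw[(offset + 1):(offset + width)]))
}

.edfNum <- function(raw, offset, width, what) {
    v <- suppressWarnings(as.numeric(.edfField(raw, offset, width)))
    if (is.na(v)) stop("malformed EDF: non-numeric header field '", what, "'")
    v
}

#' Read an EDF file (CHB-MIT dialect)
#'
#' Parses a 16-bit EDF file into an \linkS4class{EEGRecording}. All signals
#' must share one sampling rate (the CHB-MIT convention); a file whose
#' channels have differing samples-per-record counts is rejected. Seizure
#' annotations may be supplied as a companion CSV with columns
#' \code{start_s,end_s} (an optional \code{record} column is matched against
#' the EDF file name).
#'
#' @param path path to the EDF file.
#' @param annotations optional path to the companion seizure-interval CSV,
#'   or a data.frame with columns \code{start_s}, \code{end_s}.
#' @return an \linkS4class{EEGRecording}.
#' @export
readEDF <- function(path, annotations = NULL) {
    if (!file.exists(path)) stop("EDF file not found: ", path)
    sz <- file.info(path)$size
    if (sz < 256) stop("malformed EDF: file shorter than the 256-byte header")
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- readBin(con, "raw", 256L)
    nBytesHeader <- .edfNum(hdr, 184, 8, "header bytes")
    nRecords <- .edfNum(hdr, 236, 8, "record count")
    recDur <- .edfNum(hdr, 244, 8, "record duration")
    ns <- as.integer(.edfNum(hdr, 252, 4, "signal count"))
    if (ns < 1) stop("malformed EDF: no signals")
    if (nBytesHeader != 256 * (ns + 1))
        stop("malformed EDF: header size field (", nBytesHeader,
             ") inconsistent with ", ns, " signals")
    sig <- readBin(con, "raw", 256L * ns)
    fieldAt <- function(width, base) {
        vapply(seq_len(ns) - 1L,
               function(i) .edfField(sig, base * ns + i * width, width), "")
    }
    labels <- fieldAt(16, 0)
    numAt <- function(width, base, what) {
        v <- suppressWarnings(as.numeric(
            vapply(seq_len(ns) - 1L,
                   function(i) .edfField(sig, base * ns + i * width, width),
                   "")))
        if (anyNA(v))
            stop("malformed EDF: non-numeric ", what, " for signal ",
                 which(is.na(v))[1], " ('", labels[which(is.na(v))[1]], "')")
        v
    }
    # field layout after labels: transducer 80, dim 8, physMin 8, physMax 8,
    # digMin 8, digMax 8, prefilter 80, samples/record 8, reserved 32
    physMin <- numAt(8, 16 + 80 + 8, "physical minimum")
    physMax <- numAt(8, 16 + 80 + 8 + 8, "physical maximum")
    digMin <- numAt(8, 16 + 80 + 8 + 8 + 8, "digital minimum")
    digMax <- numAt(8, 16 + 80 + 8 + 8 + 8 + 8, "digital maximum")
    spr <- as.integer(numAt(8, 16 + 80 + 8 + 8 + 8 + 8 + 8 + 80,
                            "samples per record"))
    if (length(unique(spr)) != 1L)
        stop("malformed EDF: channels have mismatched samples per record (",
             paste(unique(spr), collapse = ", "), ")")
    if (any(digMax <= digMin))
        stop("malformed EDF: digital maximum must exceed digital minimum")
    recSamples <- sum(spr)
    if (nRecords < 0)                       # unspecified: infer from size
        nRecords <- floor((sz - nBytesHeader) / (2 * recSamples))
    need <- nBytesHeader + 2 * recSamples * nRecords
    if (sz < need)
        stop("malformed EDF: expected ", need, " bytes for ", nRecords,
             " records, file has ", sz)
    raw <- readBin(con, "integer", n = recSamples * nRecords, size = 2L,
                   signed = TRUE, endian = "little")
    data <- matrix(0, nrow = spr[1] * nRecords, ncol = ns)
    gain <- (physMax - physMin) / (digMax - digMin)
    for (r in seq_len(nRecords)) {
        block <- raw[((r - 1) * recSamples + 1):(r * recSamples)]
        for (s in seq_len(ns)) {
            seg <- block[((s - 1) * spr[1] + 1):(s * spr[1])]
            data[((r - 1) * spr[1] + 1):(r * spr[1]), s] <-
                (seg - digMin[s]) * gain[s] + physMin[s]
        }
    }
    # duplicated labels (e.g. 'T8P8' twice in CHB-MIT) keep their
    # acquisition index as identity
    dup <- duplicated(labels) | duplicated(labels, fromLast = TRUE)
    ids <- labels
    ids[dup] <- paste0(labels[dup], "#", stats::ave(rep(1, ns),
                       labels, FUN = cumsum)[dup])
    fs <- spr[1] / recDur
    ann <- .readAnnotations(annotations, path)
    new("EEGRecording", channels = ids, data = data, fs = fs,
        annotations = ann)
}

.readAnnotations <- function(annotations, path) {
    empty <- data.frame(start_s = numeric(0), end_s = numeric(0))
    if (is.null(annotations)) return(empty)
    ann <- if (is.data.frame(annotations)) annotations
           else utils::read.csv(annotations, stringsAsFactors = FALSE)
    if (!all(c("start_s", "end_s") %in% names(ann)))
        stop("annotation table needs columns start_s and end_s")
    if ("record" %in% names(ann))
        ann <- ann[ann$record == basename(path), , drop = FALSE]
    data.frame(start_s = as.numeric(ann$start_s),
               end_s = as.numeric(ann$end_s))
}

#' Extract one channel of a recording as labeled epochs
#'
#' Convenience wrapper: selects a channel, segments it into non-overlapping
#' fixed-length epochs and labels them against the recording's seizure
#' annotations.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param channel channel id (see \code{rec@channels}).
#' @param epochSamples samples per epoch (default: 1 s at the recording rate).
#' @param overlap overlapping samples between consecutive epochs.
#' @return a labeled \linkS4class{EpochSet}.
#' @export
recordingEpochs <- function(rec, channel = rec@channels[1],
                            epochSamples = round(rec@fs), overlap = 0L) {
    stopifnot(is(rec, "EEGRecording"))
    i <- match(channel, rec@channels)
    if (is.na(i)) stop("unknown channel '", channel, "'")
    es <- segmentSignal(rec@data[, i], n = epochSamples, overlap = overlap,
                        fs = rec@fs, channelId = channel)
    labelEpochs(es, rec@annotations)
}
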