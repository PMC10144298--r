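## Plain-text EEG input, epoch segmentation, ground-truth labeling and
## train/validation/test splitting.

#' Read a Bonn-style ASCII signal file
#'
#' Bonn EEG records are plain-text files with one numeric sample per line
#' (4097 lines per record in the original sets A-E).
#'
#' @param path path to the ASCII file.
#' @return numeric vector of all samples.
#' @export
readBonnAscii <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty signal file: ", path)
    v <- suppressWarnings(as.numeric(lines))
    if (anyNA(v))
        stop("non-numeric value at line ", which(is.na(v))[1], " of ", path,
             ": '", lines[which(is.na(v))[1]], "'")
    v
}

#' Segment a signal into fixed-length epochs
#'
#' Cuts consecutive windows of \code{n} samples with stride
#' \code{n - overlap}; a trailing partial window is dropped (the autoencoder
#' requires a fixed input length). Returns an empty set when the signal is
#' shorter than one epoch.
#'
#' @param signal numeric sample vector.
#' @param n epoch length in samples (e.g. 256 for 1 s at 256 Hz, 173 for the
#'   Bonn configuration).
#' @param overlap overlapping samples between consecutive epochs,
#'   \code{0 <= overlap < n}.
#' @param fs sampling rate in Hz (used for epoch start offsets).
#' @param channelId channel tag recorded per epoch.
#' @return an \linkS4class{EpochSet} with label \code{"unlabeled"}; epoch
#'   start times (seconds, 0-based) are in \code{colData(x)$t_start_s}.
#' @examples
#' es <- segmentSignal(sin(seq_len(2560)), n = 256)
#' nEpochs(es)  # 10
#' @export
segmentSignal <- function(signal, n, overlap = 0L, fs = n,
                          channelId = "signal") {
    n <- .assertCount(n, "n")
    if (n < 1L) stop("'n' must be >= 1")
    overlap <- .assertCount(overlap, "overlap")
    if (overlap >= n) stop("'overlap' must be smaller than 'n'")
    if (!all(is.finite(signal))) stop("signal must be finite")
    stride <- n - overlap
    starts <- seq(1L, by = stride, length.out =
                      max(0L, (length(signal) - n) %/% stride + 1L))
    if (length(signal) < n) starts <- integer(0)
    sig <- vapply(starts, function(s) signal[s:(s + n - 1L)], numeric(n))
    if (!length(starts)) sig <- matrix(numeric(0), nrow = n, ncol = 0)
    EpochSet(sig, labels = "unlabeled", fs = fs, channelId = channelId,
             tStart = (starts - 1L) / fs)
}

#' Label epochs against seizure annotations
#'
#' An epoch covering \eqn{[t, t + d)} is labeled \code{"ictal"} when it
#' overlaps a single seizure interval by at least half the epoch duration,
#' else \code{"interictal"}.
#'
#' @param epochs an \linkS4class{EpochSet} carrying \code{t_start_s}.
#' @param annotations data.frame of seizure intervals with columns
#'   \code{start_s}, \code{end_s} (zero rows: everything interictal).
#' @param minOverlap required overlap as a fraction of the epoch (default 0.5).
#' @return the \linkS4class{EpochSet} with labels replaced.
#' @export
labelEpochs <- function(epochs, annotations, minOverlap = 0.5) {
    stopifnot(is(epochs, "EpochSet"))
    dur <- epochLength(epochs) / samplingRate(epochs)
    t0 <- colData(epochs)$t_start_s
    lab <- rep("interictal", nEpochs(epochs))
    if (!is.null(annotations) && nrow(annotations)) {
        if (any(annotations$start_s >= annotations$end_s))
            stop("annotation intervals must have start < end")
        for (i in seq_len(nrow(annotations))) {
            ov <- pmin(t0 + dur, annotations$end_s[i]) -
                pmax(t0, annotations$start_s[i])
            lab[ov >= minOverlap * dur - 1e-12] <- "ictal"
        }
    }
    colData(epochs)$label <- factor(lab, levels = .EPOCH_LABELS)
    epochs
}

#' Split an epoch set into train / validation / test sets
#'
#' Seeded random assignment. Fractions must sum to 1. When
#' \code{trainClassRatio} is given (ictal fraction, interictal fraction), the
#' training set is drawn per class to match that ratio at the requested
#' training size (the corpus protocol: 40\% ictal / 60\% interictal training
#' epochs); validation and test sets keep the natural class ratio of the
#' remaining epochs.
#'
#' @param x a labeled \linkS4class{EpochSet}.
#' @param trainFraction,valFraction,testFraction proportions summing to 1.
#' @param trainClassRatio optional length-2 numeric (ictal, interictal)
#'   summing to 1.
#' @param seed integer seed for the assignment.
#' @return named list of \linkS4class{EpochSet}s: \code{train}, \code{val},
#'   \code{test}. Together they partition \code{x}.
#' @examples
#' es <- generateDataset(synthConfig(), 40, 60, seed = 5)
#' sp <- makeSplit(es, 0.7, 0.1, 0.2, seed = 5)
#' vapply(sp, nEpochs, 1L)  # 70 10 20
#' @export
makeSplit <- function(x, trainFraction = 0.7, valFraction = 0.1,
                      testFraction = 0.2, trainClassRatio = NULL, seed = 1L) {
    stopifnot(is(x, "EpochSet"))
    fr <- c(trainFraction, valFraction, testFraction)
    if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-9)
        stop("fractions must lie in [0, 1] and sum to 1")
    N <- nEpochs(x)
    nTrain <- round(trainFraction * N)
    nVal <- round(valFraction * N)
    nTest <- N - nTrain - nVal
    if (nTest < 0) { nVal <- nVal + nTest; nTest <- 0L }
    perm <- .withSeed(seed, sample.int(N))
    lab <- as.character(colData(x)$label)
    if (!is.null(trainClassRatio)) {
        if (length(trainClassRatio) != 2L ||
            abs(sum(trainClassRatio) - 1) > 1e-9)
            stop("trainClassRatio must be two fractions (ictal, interictal) summing to 1")
        nIct <- round(trainClassRatio[1] * nTrain)
        nInt <- nTrain - nIct
        ict <- perm[lab[perm] == "ictal"]
        int <- perm[lab[perm] == "interictal"]
        if (length(ict) < nIct || length(int) < nInt)
            stop("insufficient class members for the requested train ratio: ",
                 "need ", nIct, " ictal (have ", length(ict), ") and ",
                 nInt, " interictal (have ", length(int), ")")
        trainIdx <- c(ict[seq_len(nIct)], int[seq_len(nInt)])
        rest <- perm[!perm %in% trainIdx]
    } else {
        trainIdx <- perm[seq_len(nTrain)]
        rest <- perm[-seq_len(nTrain)]
    }
    valIdx <- rest[seq_len(nVal)]
    testIdx <- rest[-seq_len(nVal)]
    if (!nVal) { valIdx <- integer(0); testIdx <- rest }
    list(train = x[, sort(trainIdx)],
         val = x[, sort(valIdx)],
         test = x[, sort(testIdx)])
}

#' Write / read an epoch set as a CSV pair
#'
#' \code{writeEpochSet} stores the signal matrix (one row per epoch) and a
#' companion label table (\code{label}, \code{channel_id}, \code{t_start_s},
#' \code{fs}); \code{readEpochSet} is its inverse.
#'
#' @param x an \linkS4class{EpochSet}.
#' @param signalsFile,labelsFile output/input CSV paths.
#' @return \code{writeEpochSet}: invisibly, the two paths.
#'   \code{readEpochSet}: an \linkS4class{EpochSet}.
#' @export
writeEpochSet <- function(x, signalsFile, labelsFile) {
    stopifnot(is(x, "EpochSet"))
    utils::write.table(t(epochSignals(x)), signalsFile, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    cd <- colData(x)
    utils::write.csv(data.frame(label = as.character(cd$label),
                                channel_id = as.character(cd$channel_id),
                                t_start_s = cd$t_start_s,
                                fs = samplingRate(x)),
                     labelsFile, row.names = FALSE)
    invisible(c(signalsFile, labelsFile))
}

#' @rdname writeEpochSet
#' @export
readEpochSet <- function(signalsFile, labelsFile) {
    sig <- as.matrix(utils::read.table(signalsFile, sep = ","))
    lab <- utils::read.csv(labelsFile, stringsAsFactors = FALSE)
    if (nrow(sig) != nrow(lab))
        stop("signal and label files disagree: ", nrow(sig), " epochs vs ",
             nrow(lab), " labels")
    EpochSet(t(sig), labels = lab$label, fs = lab$fs[1],
             channelId = lab$channel_id, tStart = lab$t_start_s)
}
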