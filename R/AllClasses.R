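#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom SummarizedExperiment colData<-
#' @importFrom S4Vectors DataFrame metadata
NULL

## ---------------------------------------------------------------------------
## EpochSet
## ---------------------------------------------------------------------------

#' EpochSet: labeled fixed-length EEG epochs
#'
#' Container for a set of equal-length single-channel EEG epochs, built on
#' \link[SummarizedExperiment]{SummarizedExperiment}. The single assay
#' \code{"signal"} is a samples-by-epochs numeric matrix; per-epoch metadata
#' (class label, source channel, start offset) lives in \code{colData}; the
#' sampling rate in Hz is kept in \code{metadata(x)$fs}.
#'
#' Labels take values \code{"ictal"} (seizure, the positive class),
#' \code{"interictal"} (background) or \code{"unlabeled"}.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso \code{\link{EpochSet}} (constructor),
#'   \code{\link{generateDataset}}, \code{\link{segmentSignal}}
#' @name EpochSet-class
#' @exportClass EpochSet
setClass("EpochSet", contains = "SummarizedExperiment")

.EPOCH_LABELS <- c("interictal", "ictal", "unlabeled")

.validEpochSet <- function(object) {
    msg <- NULL
    if (!"signal" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'signal' is required")
    else if (!all(is.finite(SummarizedExperiment::assay(object, "signal"))))
        msg <- c(msg, "epoch samples must be finite")
    fs <- S4Vectors::metadata(object)$fs
    if (is.null(fs) || !is.numeric(fs) || length(fs) != 1L || fs <= 0)
        msg <- c(msg, "metadata(x)$fs must be a single positive number")
    if (!"label" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'label' column")
    else if (!all(as.character(colData(object)$label) %in% .EPOCH_LABELS))
        msg <- c(msg, "labels must be 'ictal', 'interictal' or 'unlabeled'")
    if (is.null(msg)) TRUE else msg
}

setValidity("EpochSet", .validEpochSet)

#' Construct an EpochSet
#'
#' @param signal numeric matrix, samples in rows, epochs in columns (a plain
#'   vector is treated as a single epoch).
#' @param labels character or factor of per-epoch class labels in
#'   \code{c("ictal", "interictal", "unlabeled")}; recycled if length 1.
#' @param fs sampling rate in Hz.
#' @param channelId text tag naming the source channel.
#' @param tStart numeric vector of epoch start offsets in seconds within the
#'   source recording (default: consecutive non-overlapping placement).
#' @return an \linkS4class{EpochSet}.
#' @examples
#' es <- EpochSet(matrix(rnorm(256 * 4), 256), labels = "interictal", fs = 256)
#' nEpochs(es)
#' @export
EpochSet <- function(signal, labels = "unlabeled", fs = 256,
                     channelId = "synthetic", tStart = NULL) {
    if (is.vector(signal)) signal <- matrix(signal, ncol = 1L)
    signal <- as.matrix(signal)
    storage.mode(signal) <- "double"
    ne <- ncol(signal)
    labels <- as.character(labels)
    if (length(labels) == 1L) labels <- rep(labels, ne)
    if (length(labels) != ne)
        stop("need one label per epoch (", ne, " epochs, ",
             length(labels), " labels)")
    if (is.null(tStart))
        tStart <- seq_len(ne) * (nrow(signal) / fs) - (nrow(signal) / fs)
    cd <- S4Vectors::DataFrame(
        label = factor(labels, levels = .EPOCH_LABELS),
        channel_id = rep(channelId, length.out = ne),
        t_start_s = as.numeric(tStart))
    colnames(signal) <- sprintf("epoch%04d", seq_len(ne))
    se <- SummarizedExperiment(assays = list(signal = signal), colData = cd,
                               metadata = list(fs = fs))
    new("EpochSet", se)
}

#' Accessors for EpochSet objects
#'
#' \code{epochSignals} returns the samples-by-epochs matrix;
#' \code{epochLabels} the per-epoch label factor; \code{samplingRate} the
#' sampling rate in Hz; \code{epochLength} the number of samples per epoch;
#' \code{nEpochs} the number of epochs.
#'
#' @param x an \linkS4class{EpochSet}.
#' @return see individual descriptions.
#' @name EpochSet-accessors
#' @aliases epochSignals epochLabels samplingRate epochLength nEpochs
NULL

#' @rdname EpochSet-accessors
#' @export
setMethod("epochSignals", "EpochSet",
          function(x) SummarizedExperiment::assay(x, "signal"))

#' @rdname EpochSet-accessors
#' @export
setMethod("epochLabels", "EpochSet",
          function(x) droplevels(colData(x)$label, exclude = NULL))

#' @rdname EpochSet-accessors
#' @export
setMethod("samplingRate", "EpochSet",
          function(x) S4Vectors::metadata(x)$fs)

#' @rdname EpochSet-accessors
#' @export
setMethod("epochLength", "EpochSet", function(x) nrow(x))

#' @rdname EpochSet-accessors
#' @export
setMethod("nEpochs", "EpochSet", function(x) ncol(x))

setMethod("show", "EpochSet", function(object) {
    lab <- table(colData(object)$label)
    cat("EpochSet:", ncol(object), "epochs x", nrow(object), "samples @",
        S4Vectors::metadata(object)$fs, "Hz\n")
    cat("  labels:", paste(names(lab), lab, sep = "=", collapse = ", "), "\n")
    ch <- unique(as.character(colData(object)$channel_id))
    cat("  channel:", paste(utils::head(ch, 5), collapse = ", "),
        if (length(ch) > 5) "..." else "", "\n")
})

## ---------------------------------------------------------------------------
## AEModel
## ---------------------------------------------------------------------------

#' AEModel: a trained shallow autoencoder
#'
#' Weights of a single-hidden-layer autoencoder with saturating-linear
#' (satlin) encoder activation and identity (purelin) decoder activation.
#' The encoder maps an epoch \eqn{x \in R^n} to the latent code
#' \eqn{y = satlin(W_E^T x + b_E) \in [-1,1]^m}; the decoder reconstructs
#' \eqn{\hat x = W_D^T y + b_D}.
#'
#' @slot W_E encoder weights, an \eqn{n \times m} matrix.
#' @slot b_E encoder bias, length \eqn{m}.
#' @slot W_D decoder weights, an \eqn{m \times n} matrix.
#' @slot b_D decoder bias, length \eqn{n} (all-zero when trained with
#'   \code{decoderBias = FALSE}).
#' @slot n input length (samples per epoch).
#' @slot m hidden size (latent dimensionality), \eqn{m < n}.
#' @slot encoderActivation,decoderActivation activation identifiers
#'   (\code{"satlin"}, \code{"purelin"}).
#' @seealso \code{\link{trainAE}}, \code{\link{encode}}, \code{\link{decode}}
#' @name AEModel-class
#' @exportClass AEModel
setClass("AEModel",
    representation(W_E = "matrix", b_E = "numeric",
                   W_D = "matrix", b_D = "numeric",
                   n = "integer", m = "integer",
                   encoderActivation = "character",
                   decoderActivation = "character"))

setValidity("AEModel", function(object) {
    msg <- NULL
    n <- object@n; m <- object@m
    if (m >= n) msg <- c(msg, "hidden size m must be smaller than input length n")
    if (!identical(dim(object@W_E), c(n, m)))
        msg <- c(msg, "W_E must be n x m")
    if (!identical(dim(object@W_D), c(m, n)))
        msg <- c(msg, "W_D must be m x n")
    if (length(object@b_E) != m) msg <- c(msg, "b_E must have length m")
    if (length(object@b_D) != n) msg <- c(msg, "b_D must have length n")
    ok <- all(is.finite(object@W_E)) && all(is.finite(object@W_D)) &&
        all(is.finite(object@b_E)) && all(is.finite(object@b_D))
    if (!ok) msg <- c(msg, "all parameters must be finite")
    if (object@encoderActivation != "satlin")
        msg <- c(msg, "encoder activation must be 'satlin'")
    if (object@decoderActivation != "purelin")
        msg <- c(msg, "decoder activation must be 'purelin'")
    if (is.null(msg)) TRUE else msg
})

#' @rdname AEModel-accessors
#' @export
setMethod("hiddenSize", "AEModel", function(x) x@m)

#' Accessors for AEModel objects
#'
#' @param x an \linkS4class{AEModel}.
#' @return \code{hiddenSize}: the latent dimensionality \eqn{m};
#'   \code{inputLength}: the epoch length \eqn{n}.
#' @name AEModel-accessors
#' @aliases hiddenSize inputLength
NULL

#' @rdname AEModel-accessors
#' @export
setMethod("inputLength", "AEModel", function(x) x@n)

setMethod("show", "AEModel", function(object) {
    cat("AEModel: shallow autoencoder", object@n, "->", object@m, "->",
        object@n, "\n")
    cat("  encoder:", object@encoderActivation,
        " decoder:", object@decoderActivation, "\n")
    cat("  compression ratio:", round(object@n / object@m, 2), "\n")
})

## ---------------------------------------------------------------------------
## ScgTrace
## ---------------------------------------------------------------------------

#' ScgTrace: optimization trace of a scaled-conjugate-gradient run
#'
#' @slot loss loss value after each accepted iteration (non-increasing),
#'   preceded by the initial loss.
#' @slot iterations total SCG iterations attempted (accepted + rejected).
#' @slot termination one of \code{"tol"}, \code{"max_iter"},
#'   \code{"grad_underflow"}.
#' @name ScgTrace-class
#' @exportClass ScgTrace
setClass("ScgTrace",
    representation(loss = "numeric", iterations = "integer",
                   termination = "character"))

setMethod("show", "ScgTrace", function(object) {
    cat("ScgTrace:", length(object@loss) - 1L, "accepted /",
        object@iterations, "attempted iterations;",
        "loss", format(object@loss[1]), "->",
        format(object@loss[length(object@loss)]),
        "(", object@termination, ")\n")
})

## ---------------------------------------------------------------------------
## OpCountReport
## ---------------------------------------------------------------------------

#' OpCountReport: arithmetic-operation budget of a pipeline stage
#'
#' Multiplication and addition counts (subtractions are counted as additions)
#' for one test-time evaluation, optionally broken down by stage
#' (\code{"FE"} feature extraction, \code{"CLS"} classification).
#'
#' @slot multiplications,additions operation counts.
#' @slot breakdown data.frame with columns \code{stage}, \code{multiplications},
#'   \code{additions}; sums to the totals.
#' @seealso \code{\link{aeOpCount}}, \code{\link{svmOpCount}},
#'   \code{\link{pipelineOpCount}}
#' @name OpCountReport-class
#' @exportClass OpCountReport
setClass("OpCountReport",
    representation(multiplications = "numeric", additions = "numeric",
                   breakdown = "data.frame"))

setValidity("OpCountReport", function(object) {
    msg <- NULL
    if (object@multiplications < 0 || object@additions < 0)
        msg <- c(msg, "counts must be non-negative")
    if (nrow(object@breakdown)) {
        if (!isTRUE(all.equal(sum(object@breakdown$multiplications),
                              object@multiplications)) ||
            !isTRUE(all.equal(sum(object@breakdown$additions),
                              object@additions)))
            msg <- c(msg, "breakdown must sum to the totals")
    }
    if (is.null(msg)) TRUE else msg
})

.opReport <- function(mult, add, stage = character(0)) {
    bd <- if (length(stage))
        data.frame(stage = stage, multiplications = mult, additions = add)
    else data.frame(stage = character(0), multiplications = numeric(0),
                    additions = numeric(0))
    new("OpCountReport", multiplications = sum(mult), additions = sum(add),
        breakdown = bd)
}

#' Total operation count of a report
#'
#' @param x an \linkS4class{OpCountReport}.
#' @return multiplications + additions.
#' @export
opTotal <- function(x) x@multiplications + x@additions

#' @rdname OpCountReport-class
#' @param x an \linkS4class{OpCountReport}.
#' @export
opCounts <- function(x) c(multiplications = x@multiplications,
                          additions = x@additions, total = opTotal(x))

setMethod("show", "OpCountReport", function(object) {
    cat("OpCountReport: total", format(opTotal(object), big.mark = ","),
        "(", format(object@multiplications, big.mark = ","), "mult +",
        format(object@additions, big.mark = ","), "add )\n")
    if (nrow(object@breakdown)) {
        for (i in seq_len(nrow(object@breakdown)))
            cat(sprintf("  %-4s %10s mult %10s add\n",
                        object@breakdown$stage[i],
                        format(object@breakdown$multiplications[i],
                               big.mark = ","),
                        format(object@breakdown$additions[i],
                               big.mark = ",")))
    }
})

## ---------------------------------------------------------------------------
## Classifiers
## ---------------------------------------------------------------------------

#' SeizureClassifier: fitted two-class decision function over latent features
#'
#' Virtual parent of the six classifier families. All subclasses support
#' \code{predict(object, features)} returning a label factor and, with
#' \code{type = "score"}, a numeric decision score (larger = more ictal).
#'
#' @slot family one of \code{"knn"}, \code{"svm"}, \code{"qda"}, \code{"nb"},
#'   \code{"dt"}, \code{"softmax"}.
#' @slot classes the two class labels, negative class first.
#' @slot featureDim dimensionality of the training features.
#' @name SeizureClassifier-class
#' @exportClass SeizureClassifier
setClass("SeizureClassifier", representation("VIRTUAL",
    family = "character", classes = "character", featureDim = "integer"))

#' @name KNNClassifier-class
#' @rdname SeizureClassifier-class
#' @exportClass KNNClassifier
setClass("KNNClassifier", contains = "SeizureClassifier",
    representation(X = "matrix", y = "character", k = "integer"))

#' @name SVMClassifier-class
#' @rdname SeizureClassifier-class
#' @exportClass SVMClassifier
setClass("SVMClassifier", contains = "SeizureClassifier",
    representation(SV = "matrix", coef = "numeric", b = "numeric",
                   kernelScale = "numeric", kernelOffset = "numeric",
                   boxConstraint = "numeric"))

#' @name QDAClassifier-class
#' @rdname SeizureClassifier-class
#' @exportClass QDAClassifier
setClass("QDAClassifier", contains = "SeizureClassifier",
    representation(means = "list", covInv = "list", logDet = "numeric",
                   logPrior = "numeric"))

#' @name NBClassifier-class
#' @rdname SeizureClassifier-class
#' @exportClass NBClassifier
setClass("NBClassifier", contains = "SeizureClassifier",
    representation(train = "list", bw = "list", logPrior = "numeric"))

#' @name DTClassifier-class
#' @rdname SeizureClassifier-class
#' @exportClass DTClassifier
setClass("DTClassifier", contains = "SeizureClassifier",
    representation(tree = "ANY", nodeCap = "integer"))

#' @name SoftmaxClassifier-class
#' @rdname SeizureClassifier-class
#' @exportClass SoftmaxClassifier
setClass("SoftmaxClassifier", contains = "SeizureClassifier",
    representation(w = "numeric", b = "numeric", trace = "ScgTrace"))

setMethod("show", "SeizureClassifier", function(object) {
    cat("SeizureClassifier <", object@family, "> on ", object@featureDim,
        "-dim features; classes: ", paste(object@classes, collapse = " vs "),
        "\n", sep = "")
})
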