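## Arithmetic-operation accounting of the deployed (test-time) pipeline:
## encoder-only feature extraction followed by one classifier decision.
## Multiplications and additions are counted separately; subtractions count
## as additions (standard ALU accounting).

#' Counting convention for operation reports
#'
#' @param includeBiasAdd count the encoder bias additions (default FALSE:
#'   the published AE totals follow the bias-free convention
#'   \eqn{m(2n - 1)}).
#' @param expTaylorTerms Taylor terms assumed for one exponential evaluation
#'   in the mechanistic SVM decomposition (default 10).
#' @param svmAffine length-2 numeric \code{c(slope, overhead)}: the default
#'   SVM convention counts \code{slope * d + overhead} total operations for
#'   one decision at feature dimension \code{d}. The default (15, 97) is the
#'   unique affine relation consistent with the published per-dimension SVM
#'   totals.
#' @param svmMechanistic use the mechanistic support-vector decomposition
#'   instead of the affine convention in \code{\link{decisionOps}}.
#' @return a named list.
#' @export
countingConvention <- function(includeBiasAdd = FALSE, expTaylorTerms = 10L,
                               svmAffine = c(slope = 15, overhead = 97),
                               svmMechanistic = FALSE) {
    stopifnot(expTaylorTerms >= 1, length(svmAffine) == 2)
    list(includeBiasAdd = isTRUE(includeBiasAdd),
         expTaylorTerms = as.integer(expTaylorTerms),
         svmAffine = as.numeric(svmAffine),
         svmMechanistic = isTRUE(svmMechanistic))
}

#' Encoder forward-pass operation count
#'
#' Test-time cost of encoding one epoch: the decoder is discarded after
#' training, so only \eqn{y = satlin(W_E^T x + b_E)} is evaluated. Each of
#' the \eqn{m} hidden units costs \eqn{n} multiplications and \eqn{n - 1}
#' accumulation additions; under the default convention bias additions are
#' excluded and the total is \eqn{m(2n - 1)}. Saturation is a comparison,
#' not arithmetic.
#'
#' @param n input epoch length in samples.
#' @param m hidden size, \eqn{1 \le m < n}.
#' @param conv a \code{\link{countingConvention}}.
#' @return an \linkS4class{OpCountReport} (stage \code{"FE"}).
#' @examples
#' opTotal(aeOpCount(256, 64))  # 32704
#' @export
aeOpCount <- function(n, m, conv = countingConvention()) {
    n <- .assertCount(n, "n"); m <- .assertCount(m, "m")
    if (m < 1L) stop("'m' must be >= 1")
    if (m >= n) stop("hidden size m (", m,
                     ") must be smaller than input length n (", n, ")")
    mult <- m * n
    add <- m * (n - 1) + if (conv$includeBiasAdd) m else 0
    .opReport(mult, add, "FE")
}

#' SVM decision-function operation count
#'
#' One Gaussian-kernel SVM decision at feature dimension \code{d}. The
#' default convention is affine in the feature dimension,
#' \code{slope * d + overhead} with \code{(15, 97)}, matching the published
#' per-dimension totals; the split assigns the larger halves of slope and
#' overhead to multiplications (8d + 49 mult, 7d + 48 add at the defaults).
#' Set \code{mechanistic = TRUE} for the explicit support-vector
#' decomposition (squared distance, scaled exponential via a truncated
#' Taylor series, kernel offset, weighted accumulation, bias).
#'
#' @param d feature dimension (the AE hidden size).
#' @param conv a \code{\link{countingConvention}}.
#' @param mechanistic use the support-vector decomposition.
#' @param nSV support-vector count for the mechanistic decomposition.
#' @return an \linkS4class{OpCountReport} (stage \code{"CLS"}).
#' @examples
#' opTotal(svmOpCount(64))  # 1057
#' @export
svmOpCount <- function(d, conv = countingConvention(), mechanistic = FALSE,
                       nSV = 10L) {
    d <- .assertCount(d, "d")
    if (d < 1L) stop("'d' must be >= 1")
    if (mechanistic)
        return(.svmMechanisticOps(nSV, d, conv$expTaylorTerms))
    slope <- conv$svmAffine[1]; overhead <- conv$svmAffine[2]
    mult <- ceiling(slope / 2) * d + ceiling(overhead / 2)
    add <- floor(slope / 2) * d + floor(overhead / 2)
    .opReport(mult, add, "CLS")
}

# per support vector: squared distance (d mult, d sub + d-1 add), kernel
# scale (1 mult), exp by T-term Taylor/Horner (T-1 mult, T-1 add), kernel
# offset (1 add), dual coefficient (1 mult), accumulation (1 add); plus the
# decision bias (1 add).
.svmMechanisticOps <- function(nSV, d, taylorTerms) {
    mult <- nSV * (d + 1 + (taylorTerms - 1) + 1)
    add <- nSV * (d + (d - 1) + (taylorTerms - 1) + 1 + 1) + 1
    .opReport(mult, add, "CLS")
}

#' Data reduction and compression ratio of the encoder
#'
#' @param n input epoch length.
#' @param m hidden size, \eqn{1 \le m \le n}.
#' @return list with \code{reductionPct} \eqn{= (1 - m/n) \cdot 100} and
#'   \code{compressionRatio} \eqn{= n/m}.
#' @examples
#' dataReduction(256, 64)  # 75% at ratio 4
#' @export
dataReduction <- function(n, m) {
    n <- .assertCount(n, "n"); m <- .assertCount(m, "m")
    if (m < 1L || m > n) stop("need 1 <= m <= n")
    list(reductionPct = (1 - m / n) * 100, compressionRatio = n / m)
}

#' Operation count of the full deployed pipeline
#'
#' Feature extraction (encoder forward pass) plus one classifier decision,
#' reported with an FE/CLS breakdown.
#'
#' @param n input epoch length.
#' @param m AE hidden size (= classifier feature dimension).
#' @param family classifier family, or pass a fitted classifier via
#'   \code{classifier} (required for families whose cost depends on fitted
#'   state, e.g. kNN's stored training points).
#' @param classifier optional fitted \linkS4class{SeizureClassifier}.
#' @param nTrain stored training points for \code{family = "knn"} when no
#'   classifier object is given.
#' @param conv a \code{\link{countingConvention}}.
#' @return an \linkS4class{OpCountReport} with stages \code{"FE"} and
#'   \code{"CLS"}.
#' @examples
#' pipelineOpCount(256, 32, "svm")  # FE 16352 + CLS 577
#' @export
pipelineOpCount <- function(n, m, family = c("svm", "softmax", "knn", "qda",
                                             "nb", "dt"),
                            classifier = NULL, nTrain = NULL,
                            conv = countingConvention()) {
    fe <- aeOpCount(n, m, conv)
    cls <- if (!is.null(classifier)) {
        stopifnot(is(classifier, "SeizureClassifier"))
        decisionOps(classifier, conv = conv)
    } else {
        family <- match.arg(family)
        switch(family,
            svm = svmOpCount(m, conv),
            softmax = .opReport(m, m, "CLS"),
            knn = {
                if (is.null(nTrain))
                    stop("knn operation count needs 'nTrain' or a fitted classifier")
                N <- .assertCount(nTrain, "nTrain")
                .opReport(N * m, N * m + N * (m - 1), "CLS")
            },
            stop("operation count for family '", family,
                 "' needs a fitted classifier object"))
    }
    .opReport(c(fe@multiplications, cls@multiplications),
              c(fe@additions, cls@additions), c("FE", "CLS"))
}
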