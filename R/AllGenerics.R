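#' @title Generics for SeizureAE
#' @name SeizureAE-generics
#' @description S4 generics for encoding, decoding and operation accounting.
#' @keywords internal
NULL

#' Encode epochs into the autoencoder latent space
#'
#' @param object an \linkS4class{AEModel}.
#' @param x a numeric vector (one epoch), a samples-by-epochs matrix, or an
#'   \linkS4class{EpochSet}.
#' @param ... further arguments for methods.
#' @return a matrix of latent features with one row per epoch and
#'   \code{hiddenSize(object)} columns; every entry lies in \eqn{[-1, 1]}.
#' @export
setGeneric("encode", function(object, x, ...) standardGeneric("encode"))

#' Reconstruct epochs from latent features
#'
#' @param object an \linkS4class{AEModel}.
#' @param y a numeric vector (one latent code) or an epochs-by-features matrix
#'   as returned by \code{\link{encode}}.
#' @param ... further arguments for methods.
#' @return reconstructed signal(s): a matrix with one row per epoch and
#'   \code{inputLength(object)} columns.
#' @export
setGeneric("decode", function(object, y, ...) standardGeneric("decode"))

#' Arithmetic-operation count of one decision-function evaluation
#'
#' @param object a fitted classifier.
#' @param ... further arguments (e.g. a \code{\link{countingConvention}}).
#' @return an \linkS4class{OpCountReport}.
#' @export
setGeneric("decisionOps", function(object, ...) standardGeneric("decisionOps"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("epochSignals", function(x) standardGeneric("epochSignals"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("epochLength", function(x) standardGeneric("epochLength"))

#' @rdname EpochSet-accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname AEModel-accessors
#' @export
setGeneric("hiddenSize", function(x) standardGeneric("hiddenSize"))

#' @rdname AEModel-accessors
#' @export
setGeneric("inputLength", function(x) standardGeneric("inputLength"))
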