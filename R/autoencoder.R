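## The core method: a single-hidden-layer autoencoder with saturating-linear
## encoder and linear decoder, trained by scaled conjugate gradient to
## minimize reconstruction MSE with L2 weight decay. Deployed encoder-only:
## the latent code is the feature vector handed to the classifier.

#' Saturating linear transfer function
#'
#' The symmetric saturating linear activation: identity on \eqn{[-1, 1]},
#' clipped to \eqn{-1} below and \eqn{+1} above. Used by the encoder layer so
#' every latent feature lies in \eqn{[-1, 1]}.
#'
#' @param v numeric vector or matrix.
#' @return \code{v} clipped to \eqn{[-1, 1]}, same shape as \code{v}.
#' @examples
#' satlin(c(-5, -0.3, 0, 0.25, 1.7))  # -1 -0.3 0 0.25 1
#' @export
satlin <- function(v) {
    v[v > 1] <- 1
    v[v < -1] <- -1
    v
}

# derivative of satlin: 1 on the open linear segment, 0 in saturation
.satlinDeriv <- function(z) (z > -1 & z < 1) * 1

.asSignalMatrix <- function(x) {
    if (is(x, "EpochSet")) return(epochSignals(x))
    if (is.vector(x) && is.numeric(x)) return(matrix(x, ncol = 1L))
    as.matrix(x)
}

## --- parameter packing -----------------------------------------------------

.aeUnpack <- function(theta, n, m, decoderBias) {
    W_E <- matrix(theta[seq_len(n * m)], n, m)
    o <- n * m
    b_E <- theta[o + seq_len(m)]; o <- o + m
    W_D <- matrix(theta[o + seq_len(m * n)], m, n); o <- o + m * n
    b_D <- if (decoderBias) theta[o + seq_len(n)] else numeric(n)
    list(W_E = W_E, b_E = b_E, W_D = W_D, b_D = b_D)
}

.aePack <- function(W_E, b_E, W_D, b_D, decoderBias) {
    c(as.numeric(W_E), b_E, as.numeric(W_D), if (decoderBias) b_D)
}

# loss = mean over epochs and samples of squared reconstruction error
# + l2 * sum of squared weights (biases excluded)
.aeLossTheta <- function(theta, X, n, m, l2, decoderBias) {
    p <- .aeUnpack(theta, n, m, decoderBias)
    Z <- crossprod(p$W_E, X) + p$b_E
    A <- satlin(Z)
    R <- crossprod(p$W_D, A) + p$b_D - X
    mean(R^2) + l2 * (sum(p$W_E^2) + sum(p$W_D^2))
}

.aeGradTheta <- function(theta, X, n, m, l2, decoderBias) {
    p <- .aeUnpack(theta, n, m, decoderBias)
    N <- ncol(X)
    Z <- crossprod(p$W_E, X) + p$b_E
    A <- satlin(Z)
    R <- crossprod(p$W_D, A) + p$b_D - X   # n x N residual
    dXhat <- 2 * R / (n * N)
    gW_D <- A %*% t(dXhat) + 2 * l2 * p$W_D
    gb_D <- rowSums(dXhat)
    dA <- p$W_D %*% dXhat
    dZ <- dA * .satlinDeriv(Z)
    gW_E <- X %*% t(dZ) + 2 * l2 * p$W_E
    gb_E <- rowSums(dZ)
    .aePack(gW_E, gb_E, gW_D, gb_D, decoderBias)
}

## --- public operations -----------------------------------------------------

#' @describeIn encode one epoch (numeric vector of length \eqn{n}) to a
#'   latent vector of length \eqn{m}.
#' @export
setMethod("encode", signature("AEModel", "numeric"), function(object, x) {
    if (length(x) != object@n)
        stop("epoch length ", length(x), " does not match model input length ",
             object@n)
    as.numeric(satlin(crossprod(object@W_E, x) + object@b_E))
})

#' @describeIn encode a samples-by-epochs matrix to an epochs-by-features
#'   matrix.
#' @export
setMethod("encode", signature("AEModel", "matrix"), function(object, x) {
    if (nrow(x) != object@n)
        stop("epoch length ", nrow(x), " does not match model input length ",
             object@n)
    t(satlin(crossprod(object@W_E, x) + object@b_E))
})

#' @describeIn encode an \linkS4class{EpochSet} to an epochs-by-features
#'   matrix.
#' @export
setMethod("encode", signature("AEModel", "EpochSet"),
          function(object, x) encode(object, epochSignals(x)))

#' @describeIn decode one latent vector to its reconstruction (length
#'   \eqn{n}).
#' @export
setMethod("decode", signature("AEModel", "numeric"), function(object, y) {
    if (length(y) != object@m)
        stop("latent length ", length(y), " does not match hidden size ",
             object@m)
    .callEnv$decode <- .callEnv$decode + 1L
    as.numeric(crossprod(object@W_D, y) + object@b_D)
})

#' @describeIn decode an epochs-by-features matrix to an epochs-by-samples
#'   matrix of reconstructions.
#' @export
setMethod("decode", signature("AEModel", "matrix"), function(object, y) {
    if (ncol(y) != object@m)
        stop("latent dimension ", ncol(y), " does not match hidden size ",
             object@m)
    .callEnv$decode <- .callEnv$decode + 1L
    t(crossprod(object@W_D, t(y)) + object@b_D)
})

#' Autoencoder training loss
#'
#' Mean squared reconstruction error over all epochs and samples plus an L2
#' penalty \code{l2Coeff} times the sum of squared encoder and decoder
#' weights (biases excluded).
#'
#' @param model an \linkS4class{AEModel}.
#' @param epochs an \linkS4class{EpochSet}, a samples-by-epochs matrix, or a
#'   single epoch vector.
#' @param l2Coeff L2 regularization weight.
#' @return scalar loss.
#' @export
aeLoss <- function(model, epochs, l2Coeff = 0) {
    stopifnot(is(model, "AEModel"))
    X <- .asSignalMatrix(epochs)
    if (!ncol(X)) stop("empty batch")
    if (nrow(X) != model@n)
        stop("epoch length ", nrow(X), " does not match model input length ",
             model@n)
    theta <- .aePack(model@W_E, model@b_E, model@W_D, model@b_D, TRUE)
    .aeLossTheta(theta, X, model@n, model@m, l2Coeff, TRUE)
}

#' Train a shallow autoencoder by scaled conjugate gradient
#'
#' Minimizes the reconstruction MSE with L2 weight decay over all epochs
#' (labels, if any, are ignored). Weights are initialized uniformly in
#' \eqn{\pm\sqrt{6/(n+m)}} under \code{seed}; biases start at zero. The
#' returned trace of accepted losses is non-increasing.
#'
#' @param epochs an \linkS4class{EpochSet} or samples-by-epochs matrix.
#' @param hiddenSize latent dimensionality \eqn{m < n}.
#' @param l2 L2 regularization weight (default \code{1e-4}).
#' @param maxIter SCG iteration cap.
#' @param tol relative loss-change stopping tolerance (held over 5 accepted
#'   iterations).
#' @param seed integer seed for weight initialization.
#' @param sigma0,lambda0 SCG constants (Moller's defaults).
#' @param decoderBias include the decoder bias term (default TRUE).
#' @return list with \code{model} (an \linkS4class{AEModel}) and \code{trace}
#'   (an \linkS4class{ScgTrace}).
#' @examples
#' es <- generateDataset(synthConfig(fs = 32), 5, 5, seed = 2)
#' fit <- trainAE(es, hiddenSize = 4, maxIter = 50, seed = 2)
#' fit$trace
#' @export
trainAE <- function(epochs, hiddenSize, l2 = 1e-4, maxIter = 1000L,
                    tol = 1e-8, seed = 1L, sigma0 = 1e-4, lambda0 = 1e-6,
                    decoderBias = TRUE) {
    X <- .asSignalMatrix(epochs)
    n <- nrow(X)
    m <- .assertCount(hiddenSize, "hiddenSize")
    if (m >= n) stop("hidden size m (", m, ") must be smaller than the ",
                     "epoch length n (", n, ")")
    if (m < 1L) stop("hidden size must be >= 1")
    if (!ncol(X)) stop("empty batch")
    .assertScalar(l2, "l2", 0)
    lim <- sqrt(6 / (n + m))
    theta0 <- .withSeed(seed, c(
        stats::runif(n * m, -lim, lim), numeric(m),
        stats::runif(m * n, -lim, lim), if (decoderBias) numeric(n)))
    fit <- scgOptimize(theta0,
                       fn = function(th) .aeLossTheta(th, X, n, m, l2,
                                                      decoderBias),
                       gr = function(th) .aeGradTheta(th, X, n, m, l2,
                                                      decoderBias),
                       maxIter = maxIter, tol = tol,
                       sigma0 = sigma0, lambda0 = lambda0)
    p <- .aeUnpack(fit$par, n, m, decoderBias)
    model <- new("AEModel", W_E = p$W_E, b_E = p$b_E, W_D = p$W_D,
                 b_D = p$b_D, n = as.integer(n), m = m,
                 encoderActivation = "satlin", decoderActivation = "purelin")
    list(model = model, trace = fit$trace)
}

#' Fit the feature extractor with k-fold cross-validated reconstruction error
#'
#' Runs k-fold cross-validation of \code{\link{trainAE}} to estimate the
#' held-out reconstruction MSE, then refits on all epochs. The decoder is
#' used only inside this function (to score reconstructions); the deployed
#' feature extractor is the encoder alone.
#'
#' @param epochs an \linkS4class{EpochSet} or samples-by-epochs matrix.
#' @param hiddenSize latent dimensionality.
#' @param folds number of folds (default 5, >= 2).
#' @param seed seed for fold assignment and weight initialization.
#' @param ... further arguments to \code{\link{trainAE}}.
#' @return list with \code{model} (refit on all epochs), \code{foldMSE}
#'   (held-out reconstruction MSE per fold) and \code{trace}.
#' @export
fitFeatureExtractor <- function(epochs, hiddenSize, folds = 5L, seed = 1L,
                                ...) {
    X <- .asSignalMatrix(epochs)
    folds <- .assertCount(folds, "folds")
    if (folds < 2L) stop("'folds' must be >= 2")
    N <- ncol(X)
    if (N < folds) stop("need at least as many epochs (", N,
                        ") as folds (", folds, ")")
    assign <- .withSeed(seed, sample(rep(seq_len(folds), length.out = N)))
    foldMSE <- numeric(folds)
    for (f in seq_len(folds)) {
        hold <- assign == f
        fit <- trainAE(X[, !hold, drop = FALSE], hiddenSize,
                       seed = .deriveSeed(seed, f), ...)
        Xh <- X[, hold, drop = FALSE]
        Rh <- decode(fit$model, encode(fit$model, Xh)) - t(Xh)
        foldMSE[f] <- mean(Rh^2)
    }
    final <- trainAE(X, hiddenSize, seed = seed, ...)
    list(model = final$model, foldMSE = foldMSE, trace = final$trace)
}

#' Reconstruction mean absolute error
#'
#' MAE between each epoch and its autoencoder reconstruction, and the mean
#' over epochs (the per-channel reconstruction-quality summary).
#'
#' @param model an \linkS4class{AEModel}.
#' @param epochs an \linkS4class{EpochSet}, matrix, or single epoch vector.
#' @return list with \code{perEpoch} (numeric vector) and \code{mean}.
#' @export
reconstructionMAE <- function(model, epochs) {
    stopifnot(is(model, "AEModel"))
    X <- .asSignalMatrix(epochs)
    if (nrow(X) != model@n)
        stop("epoch length ", nrow(X), " does not match model input length ",
             model@n)
    Xhat <- decode(model, encode(model, X))   # epochs x samples
    per <- rowMeans(abs(Xhat - t(X)))
    list(perEpoch = as.numeric(per), mean = mean(per))
}

## --- serialization ---------------------------------------------------------

#' Save / load an autoencoder model
#'
#' Portable JSON serialization: a header with dimensions and activation
#' identifiers plus the numeric parameter blocks. \code{readAEModel}
#' revalidates all shape invariants on load.
#'
#' @param model an \linkS4class{AEModel}.
#' @param path file path.
#' @return \code{readAEModel}: an \linkS4class{AEModel}.
#' @export
writeAEModel <- function(model, path) {
    stopifnot(is(model, "AEModel"))
    obj <- list(format = "SeizureAE/AEModel", version = 1L,
                n = model@n, m = model@m,
                encoder_activation = model@encoderActivation,
                decoder_activation = model@decoderActivation,
                W_E = as.numeric(model@W_E), b_E = model@b_E,
                W_D = as.numeric(model@W_D), b_D = model@b_D)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeAEModel
#' @export
readAEModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$format, "SeizureAE/AEModel"))
        stop("not an AE model file: ", path)
    n <- as.integer(obj$n); m <- as.integer(obj$m)
    new("AEModel", W_E = matrix(obj$W_E, n, m), b_E = as.numeric(obj$b_E),
        W_D = matrix(obj$W_D, m, n), b_D = as.numeric(obj$b_D),
        n = n, m = m, encoderActivation = obj$encoder_activation,
        decoderActivation = obj$decoder_activation)
}
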