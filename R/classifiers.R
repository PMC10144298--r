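## Six classifier families over autoencoder latent features. kNN (weighted
## vote), the SVM decision path, and softmax are implemented natively: the
## arithmetic-operation accounting and the zero-distance / tie-break rules
## depend on their exact form. SVM training is delegated to kernlab's SMO
## solver with the custom Gaussian+offset kernel; the decision tree is backed
## by rpart (Gini splits) with post-pruning to the node cap.

.CLF_FAMILIES <- c("knn", "svm", "qda", "nb", "dt", "softmax")

#' Classifier configurations
#'
#' Default hyperparameters of the classifier families: kNN with 10 Euclidean
#' nearest neighbors and squared-inverse-distance vote weights; SVM with a
#' Gaussian kernel of scale 2 plus additive kernel offset 0.1 (Gram-matrix
#' offset convention) at box constraint 1; decision tree capped at 159 nodes
#' with Gini splits.
#'
#' @param k neighbor count.
#' @param kernelScale Gaussian kernel scale \eqn{s} in
#'   \eqn{K(u,v) = \exp(-\|u-v\|^2/s^2) + offset}.
#' @param kernelOffset additive constant on each kernel evaluation.
#' @param boxConstraint SVM box constraint C.
#' @param nodeCap maximum number of tree nodes.
#' @return a named list of hyperparameters.
#' @export
knnConfig <- function(k = 10L) {
    list(k = .assertCount(k, "k"))
}

#' @rdname knnConfig
#' @export
svmConfig <- function(kernelScale = 2, kernelOffset = 0.1,
                      boxConstraint = 1) {
    list(kernelScale = .assertScalar(kernelScale, "kernelScale", 0,
                                     strict = TRUE),
         kernelOffset = .assertScalar(kernelOffset, "kernelOffset"),
         boxConstraint = .assertScalar(boxConstraint, "boxConstraint", 0,
                                       strict = TRUE))
}

#' @rdname knnConfig
#' @export
dtConfig <- function(nodeCap = 159L) {
    list(nodeCap = .assertCount(nodeCap, "nodeCap"))
}

# negative class first; "interictal" is the canonical negative class
.classOrder <- function(labels) {
    u <- unique(as.character(labels))
    if (setequal(u, c("ictal", "interictal"))) return(c("interictal", "ictal"))
    sort(u)
}

.checkFeatures <- function(features) {
    if (is.vector(features) && is.numeric(features))
        features <- matrix(features, nrow = 1L)
    features <- as.matrix(features)
    if (!all(is.finite(features))) stop("features must be finite")
    features
}

#' Fit a seizure classifier on latent features
#'
#' @param features numeric matrix, one row per epoch, one column per latent
#'   feature (as returned by \code{\link{encode}}).
#' @param labels per-row class labels (two classes; \code{"ictal"} is the
#'   positive class).
#' @param family one of \code{"knn"}, \code{"svm"}, \code{"qda"},
#'   \code{"nb"}, \code{"dt"}, \code{"softmax"}.
#' @param config optional hyperparameter list (see \code{\link{knnConfig}},
#'   \code{\link{svmConfig}}, \code{\link{dtConfig}}); defaults follow the
#'   method's stated settings.
#' @param ... passed to the softmax SCG optimizer (\code{maxIter},
#'   \code{tol}, ...).
#' @return a \linkS4class{SeizureClassifier} subclass.
#' @examples
#' es <- generateDataset(synthConfig(fs = 64), 20, 30, seed = 4)
#' ae <- trainAE(es, hiddenSize = 6, maxIter = 100, seed = 4)
#' f <- encode(ae$model, es)
#' clf <- fitClassifier(f, epochLabels(es), "knn")
#' table(predict(clf, f), epochLabels(es))
#' @export
fitClassifier <- function(features, labels,
                          family = c("knn", "svm", "qda", "nb", "dt",
                                     "softmax"),
                          config = NULL, ...) {
    family <- match.arg(family)
    X <- .checkFeatures(features)
    y <- as.character(labels)
    if (length(y) != nrow(X))
        stop("need one label per feature row")
    classes <- .classOrder(y)
    if (length(classes) > 2L) stop("only two-class problems are supported")
    if (length(classes) < 2L && family != "knn")
        stop("single-class training input is only allowed for knn")
    switch(family,
        knn = .fitKNN(X, y, classes, config),
        svm = .fitSVM(X, y, classes, config),
        qda = .fitQDA(X, y, classes),
        nb = .fitNB(X, y, classes),
        dt = .fitDT(X, y, classes, config),
        softmax = .fitSoftmax(X, y, classes, ...))
}

## --- kNN -------------------------------------------------------------------

.fitKNN <- function(X, y, classes, config) {
    config <- utils::modifyList(knnConfig(), as.list(config))
    new("KNNClassifier", family = "knn", classes = classes,
        featureDim = ncol(X), X = X, y = y, k = as.integer(config$k))
}

# weighted vote for one query; returns ictal-minus-interictal weight margin
# normalized to [-1, 1], with the exact-match and tie rules applied
.knnScore1 <- function(object, q) {
    d2 <- colSums((t(object@X) - q)^2)
    if (any(d2 == 0)) {                 # exact match: that point's label wins
        lab <- object@y[which(d2 == 0)[1]]
        return(if (lab == object@classes[length(object@classes)]) 1 else -1)
    }
    k <- min(object@k, length(d2))
    nn <- order(d2)[seq_len(k)]         # stable: ties keep stored order
    w <- 1 / d2[nn]
    pos <- object@classes[length(object@classes)]
    sPos <- sum(w[object@y[nn] == pos])
    sNeg <- sum(w[object@y[nn] != pos])
    (sPos - sNeg) / (sPos + sNeg)
}

#' Predict labels (or decision scores) for new feature vectors
#'
#' @param object a fitted \linkS4class{SeizureClassifier}.
#' @param newdata numeric feature vector or matrix (one row per epoch) of the
#'   training dimensionality.
#' @param type \code{"label"} (default) or \code{"score"}; scores are
#'   oriented so larger means more ictal, with 0 the decision threshold.
#' @return factor of labels, or numeric scores.
#' @details Ties in the kNN weighted vote (score exactly 0) go to the
#'   negative, interictal class. A kNN query at zero distance from a stored
#'   training point takes that point's label (squared-inverse weights
#'   diverge); with several zero-distance points the first in stored order
#'   wins.
#' @export
setMethod("predict", "KNNClassifier",
          function(object, newdata, type = c("label", "score")) {
    type <- match.arg(type)
    Q <- .predCheck(object, newdata)
    sc <- apply(Q, 1L, function(q) .knnScore1(object, q))
    .scoreOut(object, sc, type)
})

.predCheck <- function(object, newdata) {
    Q <- .checkFeatures(newdata)
    if (ncol(Q) != object@featureDim)
        stop("feature dimensionality ", ncol(Q),
             " does not match training dimensionality ", object@featureDim)
    Q
}

.scoreOut <- function(object, sc, type) {
    if (type == "score") return(as.numeric(sc))
    cl <- object@classes
    if (length(cl) == 1L) cl <- c(cl, cl)
    factor(ifelse(sc > 0, cl[2], cl[1]), levels = unique(cl))
}

## --- SVM -------------------------------------------------------------------

.gaussOffsetKernel <- function(scale, offset) {
    k <- function(x, y) exp(-sum((x - y)^2) / scale^2) + offset
    class(k) <- "kernel"
    k
}

.fitSVM <- function(X, y, classes, config) {
    config <- utils::modifyList(svmConfig(), as.list(config))
    kern <- .gaussOffsetKernel(config$kernelScale, config$kernelOffset)
    fit <- kernlab::ksvm(X, factor(y, levels = classes), kernel = kern,
                         C = config$boxConstraint, scaled = FALSE)
    svIdx <- kernlab::alphaindex(fit)[[1]]
    obj <- new("SVMClassifier", family = "svm", classes = classes,
               featureDim = ncol(X), SV = X[svIdx, , drop = FALSE],
               coef = as.numeric(kernlab::coef(fit)[[1]]),
               b = as.numeric(kernlab::b(fit)),
               kernelScale = config$kernelScale,
               kernelOffset = config$kernelOffset,
               boxConstraint = config$boxConstraint)
    # orient the native decision so positive scores mean the positive class
    sc <- .svmDecision(obj, X)
    agree <- mean((sc > 0) == (y == classes[2]))
    if (agree < 0.5) {
        obj@coef <- -obj@coef
        obj@b <- -obj@b
    }
    obj
}

# native decision path: f(x) = sum_i coef_i K(x, sv_i) - b with
# K(u, v) = exp(-||u-v||^2 / scale^2) + kernelOffset
.svmDecision <- function(object, Q) {
    apply(Q, 1L, function(q) {
        kv <- exp(-colSums((t(object@SV) - q)^2) / object@kernelScale^2) +
            object@kernelOffset
        sum(object@coef * kv) - object@b
    })
}

#' @rdname predict-KNNClassifier-method
#' @export
setMethod("predict", "SVMClassifier",
          function(object, newdata, type = c("label", "score")) {
    type <- match.arg(type)
    Q <- .predCheck(object, newdata)
    .scoreOut(object, .svmDecision(object, Q), type)
})

## --- QDA -------------------------------------------------------------------

.fitQDA <- function(X, y, classes) {
    m <- ncol(X)
    means <- list(); covInv <- list(); logDet <- numeric(2)
    for (i in 1:2) {
        Xi <- X[y == classes[i], , drop = FALSE]
        if (nrow(Xi) < 2L)
            stop("qda needs at least 2 training epochs per class")
        mu <- colMeans(Xi)
        Z <- sweep(Xi, 2L, mu)
        S <- crossprod(Z) / nrow(Xi)          # ML covariance
        S <- S + diag(1e-6 * sum(diag(S)) / m, m)
        ch <- tryCatch(chol(S), error = function(e)
            stop("qda covariance is singular even after ridging"))
        means[[i]] <- mu
        covInv[[i]] <- chol2inv(ch)
        logDet[i] <- 2 * sum(log(diag(ch)))
    }
    pri <- c(mean(y == classes[1]), mean(y == classes[2]))
    new("QDAClassifier", family = "qda", classes = classes,
        featureDim = m, means = means, covInv = covInv, logDet = logDet,
        logPrior = log(pri))
}

.qdaScore <- function(object, Q) {
    disc <- vapply(1:2, function(i) {
        Z <- sweep(Q, 2L, object@means[[i]])
        -0.5 * (rowSums((Z %*% object@covInv[[i]]) * Z) +
                object@logDet[i]) + object@logPrior[i]
    }, numeric(nrow(Q)))
    disc <- matrix(disc, ncol = 2)
    disc[, 2] - disc[, 1]
}

#' @rdname predict-KNNClassifier-method
#' @export
setMethod("predict", "QDAClassifier",
          function(object, newdata, type = c("label", "score")) {
    type <- match.arg(type)
    Q <- .predCheck(object, newdata)
    .scoreOut(object, .qdaScore(object, Q), type)
})

## --- naive Bayes (Gaussian kernel densities) --------------------------------

.fitNB <- function(X, y, classes) {
    train <- list(); bw <- list()
    for (i in 1:2) {
        Xi <- X[y == classes[i], , drop = FALSE]
        h <- apply(Xi, 2L, function(v) {
            b <- tryCatch(stats::bw.nrd0(v), error = function(e) NA_real_)
            if (!is.finite(b) || b <= 0)
                b <- max(stats::sd(v), 1e-3) * 0.5
            if (!is.finite(b) || b <= 0) b <- 1e-3
            b
        })
        train[[i]] <- Xi
        bw[[i]] <- h
    }
    pri <- c(mean(y == classes[1]), mean(y == classes[2]))
    new("NBClassifier", family = "nb", classes = classes,
        featureDim = ncol(X), train = train, bw = bw, logPrior = log(pri))
}

.nbScore <- function(object, Q) {
    ll <- vapply(1:2, function(i) {
        Xi <- object@train[[i]]; h <- object@bw[[i]]
        apply(Q, 1L, function(q) {
            sum(log(pmax(vapply(seq_along(q), function(j)
                mean(stats::dnorm(q[j], mean = Xi[, j], sd = h[j])),
                numeric(1)), 1e-300))) + object@logPrior[i]
        })
    }, numeric(nrow(Q)))
    ll <- matrix(ll, ncol = 2)
    ll[, 2] - ll[, 1]
}

#' @rdname predict-KNNClassifier-method
#' @export
setMethod("predict", "NBClassifier",
          function(object, newdata, type = c("label", "score")) {
    type <- match.arg(type)
    Q <- .predCheck(object, newdata)
    .scoreOut(object, .nbScore(object, Q), type)
})

## --- decision tree ----------------------------------------------------------

.fitDT <- function(X, y, classes, config) {
    config <- utils::modifyList(dtConfig(), as.list(config))
    df <- as.data.frame(X)
    names(df) <- paste0("f", seq_len(ncol(X)))
    df$.label <- factor(y, levels = classes)
    fit <- rpart::rpart(.label ~ ., data = df, method = "class",
                        control = rpart::rpart.control(cp = 0, xval = 0,
                                                       minsplit = 4))
    # prune to the node cap: smallest cp whose tree fits under the cap
    if (nrow(fit$frame) > config$nodeCap) {
        for (cp in sort(unique(fit$cptable[, "CP"]))) {
            cand <- rpart::prune(fit, cp = cp + 1e-12)
            if (nrow(cand$frame) <= config$nodeCap) { fit <- cand; break }
        }
    }
    new("DTClassifier", family = "dt", classes = classes,
        featureDim = ncol(X), tree = fit,
        nodeCap = as.integer(config$nodeCap))
}

#' @rdname predict-KNNClassifier-method
#' @export
setMethod("predict", "DTClassifier",
          function(object, newdata, type = c("label", "score")) {
    type <- match.arg(type)
    Q <- .predCheck(object, newdata)
    df <- as.data.frame(Q)
    names(df) <- paste0("f", seq_len(ncol(Q)))
    pr <- stats::predict(object@tree, df, type = "prob")
    .scoreOut(object, pr[, object@classes[2]] - 0.5, type)
})

## --- softmax (binary logistic, SCG-trained) ---------------------------------

.fitSoftmax <- function(X, y, classes, maxIter = 500L, tol = 1e-9, ...) {
    t <- as.numeric(y == classes[2])
    N <- nrow(X); m <- ncol(X)
    bce <- function(th) {
        z <- as.numeric(X %*% th[seq_len(m)]) + th[m + 1]
        # numerically stable binary cross-entropy
        mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
    }
    bceGrad <- function(th) {
        z <- as.numeric(X %*% th[seq_len(m)]) + th[m + 1]
        p <- 1 / (1 + exp(-z))
        d <- (p - t) / N
        c(as.numeric(crossprod(X, d)), sum(d))
    }
    fit <- scgOptimize(numeric(m + 1), bce, bceGrad, maxIter = maxIter,
                       tol = tol, ...)
    new("SoftmaxClassifier", family = "softmax", classes = classes,
        featureDim = m, w = fit$par[seq_len(m)], b = fit$par[m + 1],
        trace = fit$trace)
}

#' @rdname predict-KNNClassifier-method
#' @export
setMethod("predict", "SoftmaxClassifier",
          function(object, newdata, type = c("label", "score")) {
    type <- match.arg(type)
    Q <- .predCheck(object, newdata)
    .scoreOut(object, as.numeric(Q %*% object@w) + object@b, type)
})

## --- operation accounting ---------------------------------------------------

#' @describeIn decisionOps kNN over N stored points in dimension m:
#'   \eqn{Nm} subtractions (counted as additions), \eqn{Nm} multiplications,
#'   \eqn{N(m-1)} accumulation additions; neighbor selection and the vote are
#'   comparisons, not arithmetic.
#' @export
setMethod("decisionOps", "KNNClassifier", function(object, ...) {
    N <- nrow(object@X); m <- object@featureDim
    .opReport(N * m, N * m + N * (m - 1), "CLS")
})

#' @describeIn decisionOps SVM under the default Table-style affine
#'   convention at the training feature dimension (see
#'   \code{\link{svmOpCount}}); pass a \code{conv =
#'   countingConvention(svmMechanistic = TRUE)} for the mechanistic
#'   support-vector count.
#' @export
setMethod("decisionOps", "SVMClassifier",
          function(object, conv = countingConvention(), ...) {
    if (isTRUE(conv$svmMechanistic))
        .svmMechanisticOps(nrow(object@SV), object@featureDim,
                           conv$expTaylorTerms)
    else svmOpCount(object@featureDim, conv)
})

#' @describeIn decisionOps softmax: an m-term dot product plus bias
#'   (\eqn{m} multiplications, \eqn{m} additions); the monotone sigmoid is
#'   not evaluated for a threshold decision.
#' @export
setMethod("decisionOps", "SoftmaxClassifier", function(object, ...) {
    m <- object@featureDim
    .opReport(m, m, "CLS")
})

#' @describeIn decisionOps QDA: two quadratic discriminants
#'   (\eqn{m^2 + m} multiplications and \eqn{m^2 + m + 1} additions each).
#' @export
setMethod("decisionOps", "QDAClassifier", function(object, ...) {
    m <- object@featureDim
    .opReport(2 * (m^2 + m), 2 * (m * (m - 1) + m + (m - 1) + 2), "CLS")
})

#' @describeIn decisionOps kernel naive Bayes: one Gaussian kernel
#'   evaluation per training point and feature for each class (2
#'   multiplications and 2 additions per kernel under the squared-argument
#'   convention; the exponential is not expanded).
#' @export
setMethod("decisionOps", "NBClassifier", function(object, ...) {
    n1 <- nrow(object@train[[1]]); n2 <- nrow(object@train[[2]])
    m <- object@featureDim
    .opReport(2 * m * (n1 + n2), 2 * m * (n1 + n2), "CLS")
})

#' @describeIn decisionOps decision tree: threshold comparisons only, no
#'   arithmetic.
#' @export
setMethod("decisionOps", "DTClassifier", function(object, ...) {
    .opReport(0, 0, "CLS")
})

## --- serialization ----------------------------------------------------------

#' Save / load a fitted classifier
#'
#' JSON serialization of the fitted decision-function state. The rpart tree
#' of the \code{"dt"} family is embedded as a base64 block (its node table is
#' not portably flattenable); all other families are stored as plain numeric
#' arrays.
#'
#' @param object a \linkS4class{SeizureClassifier}.
#' @param path file path.
#' @return \code{readClassifier}: a \linkS4class{SeizureClassifier}.
#' @export
writeClassifier <- function(object, path) {
    stopifnot(is(object, "SeizureClassifier"))
    base <- list(format = "SeizureAE/Classifier", version = 1L,
                 family = object@family, classes = object@classes,
                 featureDim = object@featureDim)
    st <- switch(object@family,
        knn = list(X = object@X, y = object@y, k = object@k),
        svm = list(SV = object@SV, coef = object@coef, b = object@b,
                   kernelScale = object@kernelScale,
                   kernelOffset = object@kernelOffset,
                   boxConstraint = object@boxConstraint),
        qda = list(means1 = object@means[[1]], means2 = object@means[[2]],
                   covInv1 = as.numeric(object@covInv[[1]]),
                   covInv2 = as.numeric(object@covInv[[2]]),
                   logDet = object@logDet, logPrior = object@logPrior),
        nb = list(train1 = as.numeric(object@train[[1]]),
                  train2 = as.numeric(object@train[[2]]),
                  n1 = nrow(object@train[[1]]), n2 = nrow(object@train[[2]]),
                  bw1 = object@bw[[1]], bw2 = object@bw[[2]],
                  logPrior = object@logPrior),
        dt = list(tree64 = jsonlite::base64_enc(serialize(object@tree, NULL)),
                  nodeCap = object@nodeCap),
        softmax = list(w = object@w, b = object@b))
    jsonlite::write_json(c(base, st), path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeClassifier
#' @export
readClassifier <- function(path) {
    o <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(o$format, "SeizureAE/Classifier"))
        stop("not a classifier file: ", path)
    fd <- as.integer(o$featureDim)
    cl <- as.character(o$classes)
    switch(o$family,
        knn = new("KNNClassifier", family = "knn", classes = cl,
                  featureDim = fd, X = matrix(as.numeric(o$X), ncol = fd),
                  y = as.character(o$y), k = as.integer(o$k)),
        svm = new("SVMClassifier", family = "svm", classes = cl,
                  featureDim = fd, SV = matrix(as.numeric(o$SV), ncol = fd),
                  coef = as.numeric(o$coef), b = as.numeric(o$b),
                  kernelScale = o$kernelScale, kernelOffset = o$kernelOffset,
                  boxConstraint = o$boxConstraint),
        qda = new("QDAClassifier", family = "qda", classes = cl,
                  featureDim = fd,
                  means = list(as.numeric(o$means1), as.numeric(o$means2)),
                  covInv = list(matrix(as.numeric(o$covInv1), fd, fd),
                                matrix(as.numeric(o$covInv2), fd, fd)),
                  logDet = as.numeric(o$logDet),
                  logPrior = as.numeric(o$logPrior)),
        nb = new("NBClassifier", family = "nb", classes = cl,
                 featureDim = fd,
                 train = list(matrix(as.numeric(o$train1),
                                     as.integer(o$n1), fd),
                              matrix(as.numeric(o$train2),
                                     as.integer(o$n2), fd)),
                 bw = list(as.numeric(o$bw1), as.numeric(o$bw2)),
                 logPrior = as.numeric(o$logPrior)),
        dt = new("DTClassifier", family = "dt", classes = cl,
                 featureDim = fd,
                 tree = unserialize(jsonlite::base64_dec(o$tree64)),
                 nodeCap = as.integer(o$nodeCap)),
        softmax = new("SoftmaxClassifier", family = "softmax", classes = cl,
                      featureDim = fd, w = as.numeric(o$w),
                      b = as.numeric(o$b),
                      trace = new("ScgTrace", loss = NA_real_,
                                  iterations = 0L, termination = "tol")),
        stop("unknown classifier family: ", o$family))
}
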