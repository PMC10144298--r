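# Classifier families over latent features.

# independent brute-force weighted-vote kNN oracle (loops, no shared code)
bruteKNN <- function(X, y, q, k) {
    d2 <- numeric(nrow(X))
    for (i in seq_len(nrow(X))) d2[i] <- sum((X[i, ] - q)^2)
    nn <- order(d2)[seq_len(k)]
    w <- 1 / d2[nn]
    sIct <- 0; sInt <- 0
    for (j in seq_along(nn)) {
        if (y[nn[j]] == "ictal") sIct <- sIct + w[j] else sInt <- sInt + w[j]
    }
    if (sIct > sInt) "ictal" else "interictal"
}

test_that("kNN on a single-class training set predicts that class", {
    X <- matrix(rnorm(20), 10, 2)
    clf <- fitClassifier(X, rep("ictal", 10), "knn")
    expect_true(all(predict(clf, matrix(rnorm(10), 5, 2)) == "ictal"))
})

test_that("kNN exact-match, vote and tie rules", {
    # query equal to a stored point takes that point's label
    X <- rbind(c(0, 0), c(1, 1), c(2, 2))
    clf <- fitClassifier(X, c("ictal", "interictal", "interictal"), "knn",
                         config = knnConfig(k = 3))
    expect_equal(as.character(predict(clf, c(0, 0))), "ictal")
    # distances (1, 2, 2) labels (ictal, interictal, interictal):
    # weights (1, 1/4, 1/4) -> ictal wins
    X2 <- rbind(c(1, 0), c(2, 0), c(0, 2))
    clf2 <- fitClassifier(X2, c("ictal", "interictal", "interictal"),
                          "knn", config = knnConfig(k = 3))
    expect_equal(as.character(predict(clf2, c(0, 0))), "ictal")
    # exact weight tie -> interictal (negative class)
    X3 <- rbind(c(1, 0), c(-1, 0))
    clf3 <- fitClassifier(X3, c("ictal", "interictal"), "knn",
                          config = knnConfig(k = 2))
    expect_equal(as.character(predict(clf3, c(0, 0))), "interictal")
})

test_that("kNN agrees with the brute-force weighted-vote oracle", {
    for (s in 1:4) {
        set.seed(s)
        X <- matrix(rnorm(50 * 3), 50)
        y <- sample(c("ictal", "interictal"), 50, replace = TRUE)
        clf <- fitClassifier(X, y, "knn")
        Q <- matrix(rnorm(20 * 3), 20)
        got <- as.character(predict(clf, Q))
        want <- apply(Q, 1, function(q) bruteKNN(X, y, q, 10))
        expect_identical(got, want)
    }
})

test_that("SVM separates the two-blob toy exactly", {
    toy <- makeBlobs(10, seed = 3)
    clf <- fitClassifier(toy$X, toy$y, "svm")
    expect_equal(mean(as.character(predict(clf, toy$X)) == toy$y), 1)
    # decision scores have the right sign structure
    sc <- predict(clf, toy$X, type = "score")
    expect_true(all(sc[toy$y == "ictal"] > 0))
    expect_true(all(sc[toy$y == "interictal"] < 0))
})

test_that("SVM dual coefficients sum to zero so the kernel offset is absorbed", {
    toy <- makeBlobs(12, seed = 5)
    clf <- fitClassifier(toy$X, toy$y, "svm")
    expect_lt(abs(sum(clf@coef)), 1e-8)
    # changing the Gram offset shifts every decision by offset * sum(coef) = 0
    shifted <- clf
    shifted@kernelOffset <- 5
    expect_equal(predict(shifted, toy$X, type = "score"),
                 predict(clf, toy$X, type = "score"), tolerance = 1e-8)
})

test_that("softmax reaches the convex optimum found by gradient descent", {
    toy <- makeBlobs(10, seed = 7)
    clf <- fitClassifier(toy$X, toy$y, "softmax")
    expect_gte(mean(as.character(predict(clf, toy$X)) == toy$y), 0.95)
    expect_true(all(diff(clf@trace@loss) <= 1e-12))
    # decision-value comparison against a converged gradient-descent
    # reference; overlapping classes so the cross-entropy optimum is finite
    ov <- makeBlobs(20, sep = 1.5, seed = 14)
    sm <- fitClassifier(ov$X, ov$y, "softmax", maxIter = 3000, tol = 1e-14)
    t <- as.numeric(ov$y == "ictal"); X <- ov$X; N <- nrow(X)
    th <- numeric(3)
    for (i in 1:200000) {
        p <- 1 / (1 + exp(-(X %*% th[1:2] + th[3])))
        th <- th - 1.0 * c(crossprod(X, p - t) / N, mean(p - t))
    }
    zRef <- as.numeric(X %*% th[1:2] + th[3])
    expect_lt(max(abs(zRef - predict(sm, X, type = "score"))), 1e-3)
})

test_that("QDA, NB and DT separate the toy blobs", {
    toy <- makeBlobs(25, seed = 9)
    for (fam in c("qda", "nb", "dt")) {
        clf <- fitClassifier(toy$X, toy$y, fam)
        expect_gte(mean(as.character(predict(clf, toy$X)) == toy$y), 0.9,
                   label = paste(fam, "training accuracy"))
    }
    # decision tree respects its node cap
    big <- makeBlobs(100, sep = 0.5, seed = 2)   # noisy -> deep tree
    clf <- fitClassifier(big$X, big$y, "dt", config = dtConfig(nodeCap = 15))
    expect_lte(nrow(clf@tree$frame), 15)
})

test_that("single-class input errors for svm/qda/softmax but not knn", {
    X <- matrix(rnorm(20), 10, 2)
    y <- rep("ictal", 10)
    for (fam in c("svm", "qda", "softmax"))
        expect_error(fitClassifier(X, y, fam), "single-class")
    expect_s4_class(fitClassifier(X, y, "knn"), "KNNClassifier")
})

test_that("predictions are invariant to permuting the training rows", {
    set.seed(12)
    X <- matrix(rnorm(60 * 2), 60)
    y <- rep(c("ictal", "interictal"), 30)
    Q <- matrix(rnorm(15 * 2), 15)
    perm <- sample(60)
    for (fam in c("knn", "svm", "softmax", "qda", "nb")) {
        p1 <- predict(fitClassifier(X, y, fam), Q)
        p2 <- predict(fitClassifier(X[perm, ], y[perm], fam), Q)
        expect_identical(as.character(p1), as.character(p2),
                         label = paste(fam, "permutation invariance"))
    }
})

test_that("dimension mismatches are rejected at predict time", {
    toy <- makeBlobs(5, seed = 1)
    clf <- fitClassifier(toy$X, toy$y, "knn")
    expect_error(predict(clf, matrix(rnorm(9), 3, 3)), "dimensionality")
})

test_that("decision op counts follow the stated conventions", {
    toy <- makeBlobs(25, seed = 4)
    # softmax on m-dim features: m mult + m add
    Xm <- matrix(rnorm(50 * 64), 50)
    sm <- fitClassifier(Xm, rep(c("ictal", "interictal"), 25), "softmax",
                        maxIter = 5)
    ops <- decisionOps(sm)
    expect_equal(ops@multiplications, 64)
    expect_equal(ops@additions, 64)
    # knn with N stored points in dim m
    kn <- fitClassifier(toy$X, toy$y, "knn")
    oK <- decisionOps(kn)
    expect_equal(oK@multiplications, 50 * 2)
    expect_equal(oK@additions, 50 * 2 + 50 * 1)
    # svm decision ops equal the complexity module's convention
    sv <- fitClassifier(toy$X, toy$y, "svm")
    expect_equal(opCounts(decisionOps(sv)), opCounts(svmOpCount(2)))
})

test_that("classifiers round-trip through serialization", {
    toy <- makeBlobs(15, seed = 6)
    Q <- matrix(rnorm(20), 10, 2)
    for (fam in c("knn", "svm", "qda", "nb", "dt", "softmax")) {
        clf <- fitClassifier(toy$X, toy$y, fam)
        p <- tempfile(fileext = ".json")
        writeClassifier(clf, p)
        back <- readClassifier(p)
        expect_identical(as.character(predict(back, Q)),
                         as.character(predict(clf, Q)),
                         label = paste(fam, "serialization"))
    }
})
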