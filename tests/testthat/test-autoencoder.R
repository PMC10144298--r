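# Shallow autoencoder: activations, forward maps, loss, SCG training.

test_that("satlin is identity on [-1, 1] and saturates at +/-1", {
    expect_equal(satlin(1.7), 1)
    expect_equal(satlin(-5), -1)
    expect_equal(satlin(0), 0)
    expect_equal(satlin(0.25), 0.25)
    M <- matrix(c(-3, -1, 0.5, 2), 2)
    expect_equal(satlin(M), matrix(c(-1, -1, 0.5, 1), 2))
    expect_identical(dim(satlin(M)), dim(M))
})

test_that("encode computes satlin(W_E^T x + b_E)", {
    m1 <- tinyModel(W_E = matrix(c(1, -1, 0.5), 3, 1), b_E = 0.2,
                    W_D = matrix(0, 1, 3), b_D = numeric(3))
    expect_equal(encode(m1, c(2, 1, -2)), 0.2)
    m0 <- tinyModel(W_E = matrix(0, 3, 2), b_E = c(0, 0),
                    W_D = matrix(0, 2, 3), b_D = numeric(3))
    expect_equal(encode(m0, rnorm(3)), c(0, 0))
    msat <- tinyModel(W_E = matrix(c(10, 0, 0), 3, 1), b_E = 0,
                      W_D = matrix(0, 1, 3), b_D = numeric(3))
    expect_equal(encode(msat, c(1, 5, -7)), 1)
    expect_error(encode(m1, c(1, 2)), "length")
})

test_that("decode is the affine map W_D^T y + b_D", {
    m <- tinyModel(W_E = matrix(0, 2, 1), b_E = 0,
                   W_D = matrix(c(0.5, -1), 1, 2), b_D = c(0.1, 0.1))
    expect_equal(decode(m, 2), c(1.1, -1.9))
    expect_equal(decode(m, 0), c(0.1, 0.1))
    mz <- tinyModel(W_E = matrix(0, 2, 1), b_E = 0,
                    W_D = matrix(0, 1, 2), b_D = numeric(2))
    expect_equal(decode(mz, 3), c(0, 0))
    expect_error(decode(m, c(1, 2)), "latent")
})

test_that("loss is mean squared error plus weight-only L2 penalty", {
    # epochs in a 1-dim subspace reconstructed exactly by an m = 1 model
    mid <- tinyModel(W_E = matrix(c(1, 0), 2, 1), b_E = 0,
                     W_D = matrix(c(1, 2), 1, 2), b_D = numeric(2))
    X <- rbind(c(0.3, -0.2), c(0.6, -0.4))   # each epoch (a, 2a)
    expect_equal(aeLoss(mid, X, l2Coeff = 0), 0)
    # x=(1,1) reconstructed as (0,0): mean of squares = 1
    mz <- tinyModel(W_E = matrix(0, 2, 1), b_E = 0,
                    W_D = matrix(0, 1, 2), b_D = numeric(2))
    expect_equal(aeLoss(mz, c(1, 1), l2Coeff = 0), 1)
    # zero reconstruction error, 4 unit weights, l2 = 0.5 -> penalty 2
    mpen <- tinyModel(W_E = matrix(c(1, -1), 2, 1), b_E = 0,
                      W_D = matrix(c(1, -1), 1, 2), b_D = numeric(2))
    Xz <- matrix(0, 2, 3)
    expect_equal(aeLoss(mpen, Xz, l2Coeff = 0.5), 2)
    expect_error(aeLoss(mz, matrix(numeric(0), 2, 0)), "empty")
})

test_that("analytic gradient matches central finite differences", {
    for (s in 1:6) {
        set.seed(s)
        n <- sample(4:8, 1); m <- sample(1:3, 1); N <- 5
        X <- matrix(rnorm(n * N), n)
        th <- rnorm(n * m + m + m * n + n, sd = 0.6)
        g <- SeizureAE:::.aeGradTheta(th, X, n, m, 1e-4, TRUE)
        fn <- function(t) SeizureAE:::.aeLossTheta(t, X, n, m, 1e-4, TRUE)
        num <- vapply(seq_along(th), function(j) {
            h <- 1e-6; e1 <- th; e2 <- th
            e1[j] <- e1[j] + h; e2[j] <- e2[j] - h
            (fn(e1) - fn(e2)) / (2 * h)
        }, numeric(1))
        expect_lt(max(abs(g - num)) / max(abs(num)), 1e-5)
    }
})

test_that("SCG minimizes a quadratic and keeps the accepted trace monotone", {
    A <- crossprod(matrix(c(2, 0.5, 0.1, 1, 3, 0.2, 0, 0.4, 1.5), 3))
    b <- c(1, -2, 0.5)
    sol <- solve(A, b)
    fit <- scgOptimize(c(0, 0, 0),
                       fn = function(w) 0.5 * sum(w * (A %*% w)) - sum(b * w),
                       gr = function(w) as.numeric(A %*% w) - b,
                       maxIter = 200)
    expect_equal(fit$par, sol, tolerance = 1e-6, ignore_attr = TRUE)
    expect_true(all(diff(fit$trace@loss) <= 1e-12))
    expect_true(fit$trace@termination %in%
                c("tol", "grad_underflow", "max_iter"))
})

test_that("training on identical epochs drives reconstruction error to ~0", {
    set.seed(2)
    x0 <- as.numeric(scale(rnorm(16)))
    fit <- trainAE(matrix(x0, 16, 12), hiddenSize = 4, l2 = 0,
                   maxIter = 500, seed = 3)
    mse <- mean((decode(fit$model, encode(fit$model, x0)) - x0)^2)
    expect_lt(mse, 1e-6 * var(x0))
    expect_true(all(diff(fit$trace@loss) <= 1e-12))
})

test_that("epochs from a 4-dim linear subspace are reconstructed by m = 8", {
    set.seed(4)
    B <- qr.Q(qr(matrix(rnorm(32 * 4), 32)))
    X <- B %*% matrix(rnorm(4 * 200), 4)
    X <- X / max(abs(X)) * 0.9             # scale into (-1, 1)
    fit <- trainAE(X, hiddenSize = 8, l2 = 0, maxIter = 1500, seed = 5)
    rec <- decode(fit$model, encode(fit$model, X))
    expect_lt(mean((rec - t(X))^2), 0.01 * mean(X^2))
})

test_that("training is deterministic under a fixed seed", {
    X <- epochSignals(generateDataset(synthConfig(fs = 32), 5, 5, seed = 1))
    f1 <- trainAE(X, 4, maxIter = 60, seed = 9)
    f2 <- trainAE(X, 4, maxIter = 60, seed = 9)
    expect_identical(f1$model@W_E, f2$model@W_E)
    expect_identical(f1$model@b_D, f2$model@b_D)
    f3 <- trainAE(X, 4, maxIter = 60, seed = 10)
    expect_false(identical(f1$model@W_E, f3$model@W_E))
})

test_that("encoder output always lies in [-1, 1]", {
    set.seed(6)
    for (i in 1:5) {
        n <- sample(8:32, 1); m <- sample(2:6, 1)
        mod <- tinyModel(W_E = matrix(rnorm(n * m, sd = 3), n, m),
                         b_E = rnorm(m),
                         W_D = matrix(rnorm(m * n), m, n), b_D = rnorm(n))
        y <- encode(mod, matrix(rnorm(n * 7, sd = 10), n))
        expect_true(all(y >= -1 & y <= 1))
    }
})

test_that("hidden size must stay below the input length", {
    X <- matrix(rnorm(8 * 10), 8)
    expect_error(trainAE(X, 8), "smaller")
    expect_error(trainAE(X, 0), ">= 1")
})

test_that("cross-validated feature extractor reports one MSE per fold", {
    es <- generateDataset(synthConfig(fs = 32), 20, 20, seed = 2)
    fe <- fitFeatureExtractor(es, hiddenSize = 4, folds = 5, seed = 3,
                              maxIter = 80)
    expect_length(fe$foldMSE, 5)
    expect_true(all(fe$foldMSE > 0))
    fe2 <- fitFeatureExtractor(es, hiddenSize = 4, folds = 5, seed = 3,
                               maxIter = 80)
    expect_identical(fe$model@W_E, fe2$model@W_E)
    # identical epochs: held-out reconstruction is also (near) exact
    x0 <- rnorm(16)
    feI <- fitFeatureExtractor(matrix(x0, 16, 10), hiddenSize = 4,
                               folds = 2, seed = 1, l2 = 0, maxIter = 400)
    expect_lt(max(feI$foldMSE), 1e-6 * stats::var(x0))
    expect_error(fitFeatureExtractor(es, 4, folds = 1), "folds")
})

test_that("reconstruction MAE matches its definition", {
    mz <- tinyModel(W_E = matrix(0, 2, 1), b_E = 0,
                    W_D = matrix(0, 1, 2), b_D = numeric(2))
    expect_equal(reconstructionMAE(mz, c(1, -1))$mean, 1)
    mid <- tinyModel(W_E = matrix(c(1, 0), 2, 1), b_E = 0,
                     W_D = matrix(c(1, 2), 1, 2), b_D = numeric(2))
    a <- runif(3, -0.4, 0.4)
    X <- rbind(a, 2 * a)                      # each epoch (a, 2a)
    r <- reconstructionMAE(mid, X)
    expect_equal(r$perEpoch, rep(0, 3))
    # batch MAE is the mean of per-epoch MAEs
    X2 <- matrix(rnorm(8), 2)
    r2 <- reconstructionMAE(mz, X2)
    expect_equal(r2$mean, mean(r2$perEpoch))
})

test_that("AE models round-trip through JSON serialization", {
    X <- matrix(rnorm(12 * 8), 12)
    fit <- trainAE(X, 3, maxIter = 40, seed = 2)
    p <- tempfile(fileext = ".json")
    writeAEModel(fit$model, p)
    back <- readAEModel(p)
    expect_equal(back@W_E, fit$model@W_E)
    expect_equal(back@b_D, fit$model@b_D)
    expect_equal(encode(back, X[, 1]), encode(fit$model, X[, 1]))
})
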