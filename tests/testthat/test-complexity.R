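# Arithmetic-operation accounting of the deployed pipeline.

test_that("encoder op count is m(2n-1) under the default convention", {
    expect_equal(opTotal(aeOpCount(2, 1)), 3)       # 2 mult + 1 add
    r <- aeOpCount(256, 20)
    expect_equal(r@multiplications, 20 * 256)
    expect_equal(r@additions, 20 * 255)
    # bias additions enter only under the flag
    rb <- aeOpCount(256, 20, countingConvention(includeBiasAdd = TRUE))
    expect_equal(opTotal(rb), opTotal(r) + 20)
    expect_error(aeOpCount(256, 256), "smaller")
    expect_error(aeOpCount(8, 0))
})

test_that("encoder op count is additive in the hidden size", {
    for (n in c(64L, 256L)) {
        m1 <- 5L; m2 <- 11L
        expect_equal(opTotal(aeOpCount(n, m1 + m2)),
                     opTotal(aeOpCount(n, m1)) + opTotal(aeOpCount(n, m2)))
    }
})

test_that("SVM decision count is affine in the feature dimension", {
    d <- c(8L, 16L, 20L, 32L, 64L)
    tot <- vapply(d, function(x) opTotal(svmOpCount(x)), numeric(1))
    slopes <- diff(tot) / diff(d)
    expect_true(all(slopes == slopes[1]))
    # mechanistic decomposition scales with support vectors and Taylor terms
    mech10 <- svmOpCount(16, mechanistic = TRUE, nSV = 10)
    mech20 <- svmOpCount(16, mechanistic = TRUE, nSV = 20)
    expect_equal(opTotal(mech20) - 1, 2 * (opTotal(mech10) - 1))
    convT <- countingConvention(expTaylorTerms = 20)
    expect_gt(opTotal(svmOpCount(16, convT, mechanistic = TRUE)),
              opTotal(mech10))
})

test_that("data reduction and compression ratio are exact", {
    dr <- dataReduction(256, 64)
    expect_equal(dr$reductionPct, 75)
    expect_equal(dr$compressionRatio, 4)
    expect_equal(dataReduction(256, 256)$reductionPct, 0)
    expect_equal(dataReduction(256, 256)$compressionRatio, 1)
    # Bonn configuration: 173 samples encoded to 44
    drB <- dataReduction(173, 44)
    expect_equal(round(drB$reductionPct, 2), 74.57)
    expect_equal(drB$compressionRatio, 173 / 44)
    # monotone in m; CR * m = n exactly
    red <- vapply(c(8, 16, 20, 32, 64), function(m)
        dataReduction(256, m)$reductionPct, numeric(1))
    expect_true(all(diff(red) < 0))
    for (m in c(8, 16, 20, 32, 64))
        expect_equal(dataReduction(256, m)$compressionRatio * m, 256)
})

test_that("pipeline report splits FE and CLS and conserves totals", {
    r <- pipelineOpCount(256, 32, "svm")
    expect_equal(r@breakdown$stage, c("FE", "CLS"))
    fe <- r@breakdown[r@breakdown$stage == "FE", ]
    cls <- r@breakdown[r@breakdown$stage == "CLS", ]
    expect_equal(fe$multiplications + fe$additions, 16352)
    expect_equal(cls$multiplications + cls$additions, 577)
    expect_equal(opTotal(r),
                 opTotal(aeOpCount(256, 32)) + opTotal(svmOpCount(32)))
    # softmax classifier stage
    rs <- pipelineOpCount(256, 64, "softmax")
    cls2 <- rs@breakdown[rs@breakdown$stage == "CLS", ]
    expect_equal(cls2$multiplications, 64)
    expect_equal(cls2$additions, 64)
    # knn needs the stored training count
    rk <- pipelineOpCount(256, 16, "knn", nTrain = 100)
    clsK <- rk@breakdown[rk@breakdown$stage == "CLS", ]
    expect_equal(clsK$multiplications, 1600)
    expect_error(pipelineOpCount(256, 16, "knn"), "nTrain")
    # a fitted classifier supplies its own decision count
    toy <- makeBlobs(10, seed = 1)
    clf <- fitClassifier(toy$X, toy$y, "knn")
    rf <- pipelineOpCount(256, 2, classifier = clf)
    expect_equal(rf@breakdown$multiplications[2], 40)  # 20 stored points
})
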