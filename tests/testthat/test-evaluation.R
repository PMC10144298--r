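# Channel metrics and the hidden-size x classifier sweep.

test_that("confusion counts treat ictal as the positive class", {
    expect_equal(confusionCounts(c("ictal", "interictal"),
                                 c("ictal", "interictal")),
                 c(tp = 1L, fn = 0L, tn = 1L, fp = 0L))
    cc <- confusionCounts(
        c("ictal", "ictal", "interictal", "interictal", "interictal"),
        c("ictal", "interictal", "interictal", "interictal", "ictal"))
    expect_equal(cc, c(tp = 1L, fn = 1L, tn = 2L, fp = 1L))
    cc0 <- confusionCounts(rep(c("ictal", "interictal"), 3),
                           rep("interictal", 6))
    expect_equal(cc0[["tp"]], 0L)
    expect_error(confusionCounts("ictal", c("ictal", "ictal")), "length")
})

test_that("metrics follow their formulas and mark undefined cases NA", {
    m <- classMetrics(c(tp = 3, fn = 1, tn = 5, fp = 1))
    expect_equal(round(unname(m), 2), c(80, 75, 83.33))
    expect_equal(unname(classMetrics(c(tp = 4, fn = 0, tn = 6, fp = 0))),
                 c(100, 100, 100))
    m0 <- classMetrics(c(tp = 0, fn = 0, tn = 5, fp = 1))
    expect_true(is.na(m0[["sensitivity"]]))
    expect_false(is.na(m0[["specificity"]]))
    expect_true(all(is.na(classMetrics(c(tp = 0, fn = 0, tn = 0, fp = 0)))))
})

test_that("accuracy decomposes as the class-weighted mean of sen and sp", {
    set.seed(3)
    for (i in 1:20) {
        cc <- c(tp = sample(0:30, 1), fn = sample(0:30, 1),
                tn = sample(0:30, 1), fp = sample(0:30, 1))
        P <- cc[["tp"]] + cc[["fn"]]; N <- cc[["tn"]] + cc[["fp"]]
        if (P == 0 || N == 0) next
        m <- classMetrics(cc)
        expect_equal(m[["accuracy"]],
                     (m[["sensitivity"]] * P + m[["specificity"]] * N) /
                         (P + N))
    }
})

test_that("metrics tables render at two decimals with NA markers", {
    df <- data.frame(channel_id = "P8O2", accuracy = 98.855,
                     sensitivity = NA_real_, specificity = 99.125)
    out <- formatMetricsTable(df)
    expect_equal(unname(out[1, "sensitivity"]), "NA")
    expect_equal(unname(out[1, "specificity"]), "99.12")  # half-even
})

test_that("channel evaluation is deterministic and encoder-only at test time", {
    cfg <- synthConfig(fs = 64)
    train <- generateDataset(cfg, 24, 36, seed = 31)
    test <- generateDataset(cfg, 20, 30, seed = 32)
    decodeCallCount(reset = TRUE)
    ev <- evaluateChannel(train, test, hiddenSize = 8, family = "knn",
                          folds = 2, seed = 5, aeArgs = list(maxIter = 150))
    # the decoder ran only for the k-fold reconstruction estimate
    expect_equal(decodeCallCount(reset = TRUE), 2L)
    expect_true(ev$metrics$accuracy >= 0 && ev$metrics$accuracy <= 100)
    expect_equal(sum(ev$confusion), nEpochs(test))
    ev2 <- evaluateChannel(train, test, hiddenSize = 8, family = "knn",
                           folds = 2, seed = 5, aeArgs = list(maxIter = 150))
    expect_identical(ev$metrics, ev2$metrics)
})

test_that("classes identical by construction give chance-level accuracy", {
    cfg <- synthConfig(fs = 64, ictal_amp = 0)
    train <- generateDataset(cfg, 30, 30, seed = 41)
    test <- generateDataset(cfg, 50, 50, seed = 42)
    ev <- evaluateChannel(train, test, hiddenSize = 8, family = "knn",
                          folds = 2, seed = 5, aeArgs = list(maxIter = 150))
    # 99% binomial interval around 50% at n = 100
    expect_lt(abs(ev$metrics$accuracy - 50), 2.576 * 50 / sqrt(100) + 1e-9)
})

test_that("sweep covers the grid, averages channels and picks best sizes", {
    cfg <- synthConfig(fs = 64)
    chans <- list(
        chA = list(train = generateDataset(cfg, 16, 24, seed = 51,
                                           channelId = "chA"),
                   test = generateDataset(cfg, 20, 30, seed = 52,
                                          channelId = "chA")),
        chB = list(train = generateDataset(cfg, 16, 24, seed = 53,
                                           channelId = "chB"),
                   test = generateDataset(cfg, 20, 30, seed = 54,
                                          channelId = "chB")))
    sw <- sweepGrid(chans, hiddenSizes = c(8, 4), families = "knn",
                    folds = 2, aeArgs = list(maxIter = 100), seed = 2)
    expect_equal(nrow(sw$cells), 4)
    expect_equal(nrow(sw$means), 2)
    expect_equal(sw$means$hidden_size, c(8, 4))   # requested grid order
    expect_equal(sw$means$accuracy[1],
                 mean(sw$cells$accuracy[sw$cells$hidden_size == 8]))
    # per-channel argmax; metric ties break toward the larger hidden size
    expect_equal(nrow(sw$bestHidden), 6)
    for (i in seq_len(nrow(sw$bestHidden))) {
        ch <- sw$bestHidden$channel_id[i]
        met <- sw$bestHidden$metric[i]
        sub <- sw$cells[sw$cells$channel_id == ch, ]
        best <- max(sub$hidden_size[sub[[met]] >= max(sub[[met]]) - 1e-12])
        expect_equal(sw$bestHidden$best_hidden_size[i], best)
    }
    # single-cell grid
    sw1 <- sweepGrid(chans["chA"], hiddenSizes = 8, families = "knn",
                     folds = 2, aeArgs = list(maxIter = 100), seed = 2)
    expect_equal(nrow(sw1$means), 1)
    expect_error(sweepGrid(list(), 8, "knn"), "empty")
})

test_that("sweep cells reproduce an independent single evaluation", {
    cfg <- synthConfig(fs = 64)
    chans <- list(ch = list(
        train = generateDataset(cfg, 16, 24, seed = 61, channelId = "ch"),
        test = generateDataset(cfg, 20, 30, seed = 62, channelId = "ch")))
    sw <- sweepGrid(chans, hiddenSizes = 8, families = "knn", folds = 2,
                    aeArgs = list(maxIter = 100), seed = 7)
    ev <- evaluateChannel(chans$ch$train, chans$ch$test, hiddenSize = 8,
                          family = "knn", folds = 2,
                          seed = SeizureAE:::.deriveSeed(7, 1L),
                          channelId = "ch", aeArgs = list(maxIter = 100))
    expect_equal(sw$cells$accuracy, ev$metrics$accuracy)
    expect_equal(sw$cells$sensitivity, ev$metrics$sensitivity)
})
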