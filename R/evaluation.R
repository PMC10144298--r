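## Channel-wise performance metrics (ictal = positive class) and the
## hidden-size x classifier sweep that produces the per-channel and averaged
## report shapes.

#' Confusion counts with ictal as the positive class
#'
#' @param labels true labels (\code{"ictal"} / \code{"interictal"}).
#' @param predictions predicted labels, same length.
#' @return named integer vector with \code{tp}, \code{fn}, \code{tn},
#'   \code{fp}; sums to the number of evaluated epochs.
#' @examples
#' confusionCounts(c("ictal", "ictal", "interictal"),
#'                 c("ictal", "interictal", "interictal"))
#' @export
confusionCounts <- function(labels, predictions) {
    labels <- as.character(labels)
    predictions <- as.character(predictions)
    if (length(labels) != length(predictions))
        stop("labels and predictions must have equal length (",
             length(labels), " vs ", length(predictions), ")")
    if (!all(labels %in% c("ictal", "interictal")))
        stop("labels must be 'ictal' or 'interictal'")
    pos <- labels == "ictal"
    phat <- predictions == "ictal"
    c(tp = sum(pos & phat), fn = sum(pos & !phat),
      tn = sum(!pos & !phat), fp = sum(!pos & phat))
}

#' Accuracy, sensitivity and specificity in percent
#'
#' \eqn{sen = tp/(tp+fn) \cdot 100} (true-positive rate on ictal epochs),
#' \eqn{sp = tn/(tn+fp) \cdot 100}, \eqn{acc = (tp+tn)/total \cdot 100}.
#' A metric whose denominator is empty is \code{NA}, never 0.
#'
#' @param counts a vector as returned by \code{\link{confusionCounts}}.
#' @return named numeric vector \code{accuracy}, \code{sensitivity},
#'   \code{specificity} on \eqn{[0, 100]}.
#' @examples
#' classMetrics(c(tp = 3, fn = 1, tn = 5, fp = 1))
#' @export
classMetrics <- function(counts) {
    tp <- counts[["tp"]]; fn <- counts[["fn"]]
    tn <- counts[["tn"]]; fp <- counts[["fp"]]
    total <- tp + fn + tn + fp
    c(accuracy = if (total > 0) (tp + tn) / total * 100 else NA_real_,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) * 100 else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) * 100 else NA_real_)
}

#' Evaluate one channel: autoencoder features plus one classifier
#'
#' The per-channel protocol: fit the feature extractor on the training
#' epochs (k-fold cross-validated reconstruction error, refit on all), encode
#' both sets, fit the classifier on the encoded training epochs, predict the
#' test epochs and compute the channel metrics. Classification is
#' encoder-only; the decoder is never evaluated on the test path.
#'
#' @param train,test labeled \linkS4class{EpochSet}s sharing one epoch
#'   length.
#' @param hiddenSize AE hidden size.
#' @param family classifier family (see \code{\link{fitClassifier}}).
#' @param clfConfig optional classifier hyperparameter list.
#' @param folds folds for AE cross-validation.
#' @param seed integer seed (AE init and folds derive from it).
#' @param channelId report tag; defaults to the training set's channel.
#' @param aeArgs further arguments to \code{\link{trainAE}} (e.g. \code{l2},
#'   \code{maxIter}).
#' @return list with \code{metrics} (one-row data.frame: channel, hidden
#'   size, family, accuracy, sensitivity, specificity), \code{confusion},
#'   \code{model}, \code{classifier}, \code{foldMSE}.
#' @export
evaluateChannel <- function(train, test, hiddenSize, family = "knn",
                            clfConfig = NULL, folds = 5L, seed = 1L,
                            channelId = NULL, aeArgs = list()) {
    stopifnot(is(train, "EpochSet"), is(test, "EpochSet"))
    if (epochLength(train) != epochLength(test))
        stop("train and test sets must share one epoch length")
    if (is.null(channelId))
        channelId <- as.character(colData(train)$channel_id[1])
    fe <- do.call(fitFeatureExtractor,
                  c(list(epochs = train, hiddenSize = hiddenSize,
                         folds = folds, seed = seed), aeArgs))
    ftr <- encode(fe$model, train)
    fte <- encode(fe$model, test)
    clf <- fitClassifier(ftr, epochLabels(train), family = family,
                         config = clfConfig)
    pred <- predict(clf, fte)
    cc <- confusionCounts(epochLabels(test), pred)
    met <- classMetrics(cc)
    list(metrics = data.frame(channel_id = channelId,
                              hidden_size = hiddenSize, family = family,
                              accuracy = met[["accuracy"]],
                              sensitivity = met[["sensitivity"]],
                              specificity = met[["specificity"]]),
         confusion = cc, model = fe$model, classifier = clf,
         foldMSE = fe$foldMSE)
}

#' Hidden-size by classifier sweep over channels
#'
#' Runs \code{\link{evaluateChannel}} over the full grid of AE hidden sizes
#' and classifier families for every channel, and summarizes: per-cell
#' channel means, and for each channel and metric the hidden size achieving
#' the best value (argmax; ties break toward the larger hidden size).
#'
#' @param channels named list; each element a list with \code{train} and
#'   \code{test} \linkS4class{EpochSet}s.
#' @param hiddenSizes integer vector of AE hidden sizes (the published grid
#'   is \code{c(64, 32, 20, 16, 8)}).
#' @param families character vector of classifier families.
#' @param seed master seed; each (channel, size, family) cell derives its
#'   own seed deterministically.
#' @param ... passed to \code{\link{evaluateChannel}}.
#' @return list with \code{cells} (all per-channel rows), \code{means}
#'   (per hidden size and family, averaged over channels) and
#'   \code{bestHidden} (per channel and metric).
#' @export
sweepGrid <- function(channels, hiddenSizes = c(64, 32, 20, 16, 8),
                      families = "knn", seed = 1L, ...) {
    if (!length(channels) || !length(hiddenSizes) || !length(families))
        stop("empty sweep grid")
    if (is.null(names(channels)))
        names(channels) <- paste0("channel", seq_along(channels))
    cells <- list()
    cellId <- 0L
    for (ch in names(channels)) {
        for (m in hiddenSizes) {
            for (fam in families) {
                cellId <- cellId + 1L
                ev <- evaluateChannel(channels[[ch]]$train,
                                      channels[[ch]]$test,
                                      hiddenSize = m, family = fam,
                                      seed = .deriveSeed(seed, cellId),
                                      channelId = ch, ...)
                cells[[cellId]] <- ev$metrics
            }
        }
    }
    cells <- do.call(rbind, cells)
    means <- stats::aggregate(
        cells[, c("accuracy", "sensitivity", "specificity")],
        by = list(hidden_size = cells$hidden_size, family = cells$family),
        FUN = mean)
    # keep the requested grid ordering
    means <- means[order(match(means$hidden_size, hiddenSizes),
                         match(means$family, families)), , drop = FALSE]
    rownames(means) <- NULL
    bestHidden <- do.call(rbind, lapply(names(channels), function(ch) {
        sub <- cells[cells$channel_id == ch, , drop = FALSE]
        do.call(rbind, lapply(c("accuracy", "sensitivity", "specificity"),
            function(metric) {
                agg <- stats::aggregate(sub[[metric]],
                    by = list(hidden_size = sub$hidden_size), FUN = max)
                best <- agg$hidden_size[agg$x >= max(agg$x) - 1e-12]
                data.frame(channel_id = ch, metric = metric,
                           best_hidden_size = max(best),
                           value = max(agg$x))
            }))
    }))
    list(cells = cells, means = means, bestHidden = bestHidden)
}

#' Format a metrics table the way the channel reports print it
#'
#' Renders metric columns to 2 decimal places with half-even rounding;
#' undefined metrics print as \code{"NA"}.
#'
#' @param df a data.frame with metric columns (percent scale).
#' @param file optional path: write as CSV.
#' @return character matrix (invisibly when writing to file).
#' @export
formatMetricsTable <- function(df, file = NULL) {
    out <- df
    for (cn in intersect(c("accuracy", "sensitivity", "specificity"),
                         names(out)))
        out[[cn]] <- ifelse(is.na(df[[cn]]), "NA",
                            formatC(round(df[[cn]], 2), format = "f",
                                    digits = 2))
    if (!is.null(file)) {
        utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
        return(invisible(as.matrix(out)))
    }
    as.matrix(out)
}
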