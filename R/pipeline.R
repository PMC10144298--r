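## End-to-end orchestration: a YAML config drives simulate/load -> split ->
## train AE -> encode -> train classifier -> evaluate -> opcount, leaving a
## run directory with every intermediate artifact and a manifest.

.stageTry <- function(stage, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

.loadDatasetFromConfig <- function(ds, seed) {
    type <- ds$type %||% "synthetic"
    if (type == "synthetic") {
        cfg <- synthConfig(
            fs = ds$fs %||% 256, epoch_len_s = ds$epoch_len_s %||% 1,
            background_model = ds$background_model %||% "ar2",
            background_sd = ds$background_sd %||% 1,
            ictal_freq_hz = ds$ictal_freq_hz %||% 3,
            ictal_amp = ds$ictal_amp %||% 5,
            ictal_duty = ds$ictal_duty %||% 1,
            seed = ds$seed %||% seed)
        generateDataset(cfg, nIctal = ds$n_ictal %||% 40,
                        nInterictal = ds$n_interictal %||% 60,
                        seed = ds$seed %||% seed)
    } else if (type == "csv") {
        readEpochSet(ds$signals, ds$labels)
    } else if (type == "edf") {
        rec <- readEDF(ds$path, annotations = ds$annotations)
        recordingEpochs(rec, channel = ds$channel %||% rec@channels[1],
                        epochSamples = ds$epoch_samples %||% round(rec@fs))
    } else if (type == "ascii") {
        sig <- readBonnAscii(ds$path)
        segmentSignal(sig, n = ds$epoch_samples %||% 173,
                      fs = ds$fs %||% 173.61,
                      channelId = ds$channel %||% basename(ds$path))
    } else stop("unknown dataset type: ", type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full detection pipeline from a configuration
#'
#' Executes simulate/load, split, autoencoder training, encoding, classifier
#' training, test-set evaluation and operation accounting, writing each
#' artifact plus a machine-readable manifest (seeds, artifact checksums,
#' package version) into \code{outDir}. Reruns with the same configuration
#' and seed are identical.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list. Sections: \code{dataset} (type \code{synthetic}/\code{csv}/
#'   \code{edf}/\code{ascii} and its parameters), \code{split}
#'   (\code{train}/\code{val}/\code{test} fractions,
#'   \code{train_class_ratio}), \code{ae} (\code{hidden_size}, \code{l2},
#'   \code{folds}, \code{max_iter}), \code{classifier} (\code{family},
#'   hyperparameters).
#' @param outDir run directory (created if missing).
#' @param seed master seed; every stage derives its own stream from it.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, outDir, seed = 1L) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(config$seed %||% seed)

    ae <- config$ae %||% list()
    m <- as.integer(ae$hidden_size %||% 16)

    data <- .stageTry("dataset", .loadDatasetFromConfig(config$dataset,
                                                        seed))
    if (m >= epochLength(data))
        stop("pipeline stage 'validate' failed: hidden size (", m,
             ") must be smaller than the epoch length (",
             epochLength(data), ")", call. = FALSE)

    sp <- config$split %||% list()
    split <- .stageTry("split", makeSplit(
        data, trainFraction = sp$train %||% 0.7,
        valFraction = sp$val %||% 0.1, testFraction = sp$test %||% 0.2,
        trainClassRatio = unlist(sp$train_class_ratio),
        seed = .deriveSeed(seed, 1L)))

    fe <- .stageTry("train-ae", fitFeatureExtractor(
        split$train, hiddenSize = m, folds = ae$folds %||% 5L,
        seed = .deriveSeed(seed, 2L), l2 = ae$l2 %||% 1e-4,
        maxIter = ae$max_iter %||% 1000L))
    modelPath <- file.path(outDir, "ae_model.json")
    writeAEModel(fe$model, modelPath)

    feat <- .stageTry("encode", list(
        train = encode(fe$model, split$train),
        test = encode(fe$model, split$test)))
    featPath <- file.path(outDir, "features_train.csv")
    utils::write.csv(feat$train, featPath, row.names = FALSE)
    featTestPath <- file.path(outDir, "features_test.csv")
    utils::write.csv(feat$test, featTestPath, row.names = FALSE)

    clfCfg <- config$classifier %||% list()
    family <- clfCfg$family %||% "knn"
    clf <- .stageTry("train-clf", fitClassifier(
        feat$train, epochLabels(split$train), family = family,
        config = clfCfg$config))
    clfPath <- file.path(outDir, "classifier.json")
    writeClassifier(clf, clfPath)

    metrics <- .stageTry("evaluate", {
        pred <- predict(clf, feat$test)
        cc <- confusionCounts(epochLabels(split$test), pred)
        met <- classMetrics(cc)
        data.frame(channel_id = as.character(colData(split$test)$channel_id[1]),
                   hidden_size = m, family = family,
                   accuracy = met[["accuracy"]],
                   sensitivity = met[["sensitivity"]],
                   specificity = met[["specificity"]],
                   tp = cc[["tp"]], fn = cc[["fn"]], tn = cc[["tn"]],
                   fp = cc[["fp"]])
    })
    metricsPath <- file.path(outDir, "metrics.csv")
    utils::write.csv(metrics, metricsPath, row.names = FALSE)

    ops <- .stageTry("opcount", pipelineOpCount(
        n = epochLength(data), m = m, classifier = clf))
    opsPath <- file.path(outDir, "opcount.json")
    jsonlite::write_json(list(
        multiplications = ops@multiplications, additions = ops@additions,
        total = opTotal(ops), breakdown = ops@breakdown),
        opsPath, digits = NA, auto_unbox = TRUE)

    artifacts <- c(ae_model = modelPath, features_train = featPath,
                   features_test = featTestPath, classifier = clfPath,
                   metrics = metricsPath, opcount = opsPath)
    manifest <- list(
        package = "SeizureAE",
        version = as.character(utils::packageVersion("SeizureAE")),
        seed = seed,
        stage_seeds = list(split = .deriveSeed(seed, 1L),
                           ae = .deriveSeed(seed, 2L)),
        config = config,
        n_epochs = nEpochs(data),
        epoch_length = epochLength(data),
        hidden_size = m, family = family,
        artifacts = lapply(artifacts, function(p)
            list(path = basename(p), md5 = unname(tools::md5sum(p)))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
    invisible(manifest)
}
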