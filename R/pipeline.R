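#' @include phantom.R feature_stack.R model.R train.R losses_metrics.R
NULL

#' Construct a RunConfig for the end-to-end pipeline
#'
#' Describes one reproducible run: where the data come from (a manifest of
#' NIfTI cases, or the built-in phantom generator when `manifest` is NULL),
#' which handcrafted features to extract, the fusion strategy, and the model
#' / training / augmentation sub-configurations.
#'
#' @param outDir run directory for artifacts (checkpoints, predictions,
#'   metrics, logs).
#' @param manifest optional manifest CSV path; NULL simulates phantoms.
#' @param nCases number of phantom cases when simulating.
#' @param imageSize phantom image side (and network input size), pixels.
#' @param features handcrafted feature selection, subset of
#'   c("hog", "dsurf", "texture"); ignored when `fusion = "none"`.
#' @param fusion fusion strategy passed to [hybridModelConfig()].
#' @param encoderChannels encoder widths.
#' @param trainFraction train/test split fraction.
#' @param train a [trainConfig()].
#' @param augment optional [augmentationConfig()]; NULL disables.
#' @param fineTune run the reduced-learning-rate fine-tuning pass after
#'   initial training.
#' @param seed master seed for simulation, splitting and training.
#' @return classed list of class "RunConfig".
#' @export
runConfig <- function(outDir, manifest = NULL, nCases = 64L, imageSize = 64L,
                      features = "hog", fusion = "decision_level",
                      encoderChannels = c(8L, 16L, 32L, 64L),
                      trainFraction = 0.7,
                      train = trainConfig(epochs = 30L, seed = seed),
                      augment = NULL, fineTune = TRUE, seed = 1L) {
  structure(list(outDir = outDir, manifest = manifest,
                 nCases = as.integer(nCases),
                 imageSize = as.integer(imageSize), features = features,
                 fusion = fusion, encoderChannels = as.integer(encoderChannels),
                 trainFraction = trainFraction, train = train,
                 augment = augment, fineTune = fineTune,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

.loadManifestItems <- function(manifestPath, targetSize) {
  mf <- readManifest(manifestPath)
  items <- list()
  for (i in seq_len(nrow(mf))) {
    vol <- readVolume(c(t1 = mf$t1[i], t1c = mf$t1c[i], t2 = mf$t2[i],
                        flair = mf$flair[i]))
    vol <- normalizeIntensity(vol)
    msk <- readMask(mf$mask[i])
    lab <- maskLabels(msk)
    if (length(dim(lab)) == 2L)   # single-slice case file
      msk <- SegmentationMask(array(lab, dim = c(1L, dim(lab))))
    pairs <- sliceDataset(vol, msk, targetSize = targetSize)
    for (p in pairs) {
      p$case <- mf$case_id[i]
      items[[length(items) + 1L]] <- p
    }
  }
  items
}

#' Run the full segmentation pipeline
#'
#' Executes simulate-or-load, preprocessing, handcrafted feature
#' extraction, hybrid model construction, training, fine-tuning, test-set
#' prediction and evaluation, writing all artifacts (config echo, training
#' history, model checkpoint, predicted masks as NIfTI, metrics JSON and
#' per-case CSV) into the run directory. Fully reproducible given the
#' config seeds.
#'
#' @param config a [runConfig()].
#' @param verbose print stage progress.
#' @return list with `report` (a [MetricsReport-class]), `history`,
#'   `finetuneHistory` (or NULL) and `model`, invisibly.
#' @examples
#' \dontrun{
#' cfg <- runConfig(outDir = "run1", nCases = 64, imageSize = 64,
#'                  fusion = "decision_level", seed = 1)
#' res <- runPipeline(cfg, verbose = TRUE)
#' res$report
#' }
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(config$outDir, "run.log")
  say <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(fmt, ...))
    cat(msg, "\n", file = log, append = TRUE)
    if (verbose) message(msg)
  }

  say("stage: data (%s)",
      if (is.null(config$manifest)) "simulate phantoms" else config$manifest)
  items <- if (is.null(config$manifest)) {
    spec <- phantomSpec(imageSize = config$imageSize, seed = config$seed)
    generatePhantomDataset(spec, config$nCases, seed = config$seed)
  } else {
    .loadManifestItems(config$manifest, config$imageSize)
  }
  for (i in seq_along(items))
    if (is.null(items[[i]]$case)) items[[i]]$case <- sprintf("case%03d", i)

  k <- 0L
  if (config$fusion != "none") {
    say("stage: handcrafted features (%s)",
        paste(config$features, collapse = "+"))
    for (i in seq_along(items)) {
      items[[i]]$features <- extractFeatures(items[[i]]$slice,
                                             features = config$features)
    }
    k <- nChannels(items[[1]]$features)
  }

  say("stage: split (fraction %.2f)", config$trainFraction)
  sp <- splitDataset(seq_along(items), config$trainFraction,
                     seed = .deriveSeed(config$seed, 11L))
  trainItems <- items[sp$train]
  testItems <- items[sp$test]

  say("stage: build model (fusion %s, k=%d)", config$fusion, k)
  mcfg <- hybridModelConfig(inputSize = config$imageSize, inChannels = 4L,
                            encoderChannels = config$encoderChannels,
                            nClasses = 4L, fusion = config$fusion,
                            handcraftedChannels = k)
  model <- if (config$fusion == "none") {
    buildCNN(mcfg, seed = .deriveSeed(config$seed, 21L))
  } else {
    buildHybrid(mcfg, seed = .deriveSeed(config$seed, 21L))
  }

  # with augmentation on, handcrafted features are re-extracted from each
  # augmented slice so the fused channels track the warped geometry
  featureFn <- if (!is.null(config$augment) && config$fusion != "none") {
    function(slice) extractFeatures(slice, features = config$features)
  } else NULL

  say("stage: train (%d epochs max)", config$train@epochs)
  tr <- trainModel(model, trainItems, config = config$train,
                   augment = config$augment, featureFn = featureFn,
                   verbose = verbose)
  model <- tr$model
  ftHistory <- NULL
  if (config$fineTune) {
    say("stage: fine-tune (lr/10)")
    ft <- finetuneModel(model, trainItems, baseConfig = config$train,
                        augment = config$augment, featureFn = featureFn,
                        verbose = verbose)
    model <- ft$model
    ftHistory <- ft$history
  }

  say("stage: predict + evaluate (%d test items)", length(testItems))
  preds <- lapply(testItems, function(it)
    forwardPredict(model, it$slice,
                   featureStacks = if (is.null(it$features)) NULL
                                   else list(it$features)))
  report <- evaluateDataset(preds, lapply(testItems, `[[`, "mask"))

  say("stage: artifacts")
  predDir <- file.path(config$outDir, "predictions")
  dir.create(predDir, showWarnings = FALSE)
  for (i in seq_along(preds)) {
    lab <- preds[[i]]@labels
    writeMask(SegmentationMask(array(lab, dim = c(1L, dim(lab)))),
              file.path(predDir, sprintf("%s_pred.nii.gz",
                                         testItems[[i]]$case)))
  }
  saveModel(model, file.path(config$outDir, "model.rds"))
  utils::write.csv(as.data.frame(tr$history),
                   file.path(config$outDir, "history.csv"),
                   row.names = FALSE)
  if (!is.null(ftHistory))
    utils::write.csv(as.data.frame(ftHistory),
                     file.path(config$outDir, "history_finetune.csv"),
                     row.names = FALSE)
  metricsJSON(report, file.path(config$outDir, "metrics.json"))
  writeMetricsCSV(report, file.path(config$outDir, "metrics_per_case.csv"))
  cfgEcho <- config
  cfgEcho$train <- .echoConfig(config$train)
  cfgEcho$augment <- if (is.null(config$augment)) NULL else
    attributes(config$augment)
  yaml::write_yaml(lapply(unclass(cfgEcho), function(x)
    if (is.atomic(x) || is.null(x)) x else "<object>"),
    file.path(config$outDir, "config.yaml"))
  say("done")
  invisible(list(report = report, history = tr$history,
                 finetuneHistory = ftHistory, model = model))
}
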