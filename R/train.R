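#' @include AllClasses.R model.R losses_metrics.R augment.R
NULL

#' Construct a TrainConfig
#'
#' Defaults follow the published recipe: SGD with momentum 0.9, learning
#' rate 0.0010, weight decay 0.0005, batch size 16, up to 100 epochs, early
#' stopping with patience 10 on the validation loss.
#'
#' @param momentum,learningRate,weightDecay,batchSize,epochs,patience,seed
#'   see [TrainConfig-class].
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(momentum = 0.9, learningRate = 0.0010,
                        weightDecay = 0.0005, batchSize = 16L,
                        epochs = 100L, patience = 10L, seed = 1L) {
  cfg <- new("TrainConfig", momentum = momentum, learningRate = learningRate,
             weightDecay = weightDecay, batchSize = as.integer(batchSize),
             epochs = as.integer(epochs), patience = as.integer(patience),
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

#' Split case ids into train and test partitions
#'
#' Ids are shuffled by `seed`; the first `round(trainFraction * n)` form the
#' training set. The partitions are disjoint and exhaustive. 285 ids at
#' fraction 0.70 give the conventional 200/85 split.
#'
#' @param caseIds vector of unique case identifiers.
#' @param trainFraction fraction in (0, 1).
#' @param seed shuffle seed.
#' @return `list(train = ..., test = ...)`.
#' @export
splitDataset <- function(caseIds, trainFraction = 0.7, seed = 1L) {
  if (anyDuplicated(caseIds)) stop("non-unique cases")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  shuffled <- .withSeed(seed, sample(caseIds))
  nTrain <- round(trainFraction * length(caseIds))
  list(train = shuffled[seq_len(nTrain)],
       test = shuffled[setdiff(seq_along(caseIds), seq_len(nTrain))])
}

#' Early-stopping rule
#'
#' Given per-epoch validation losses, returns the epoch after which training
#' stops: the first epoch lying `patience` epochs past the best-so-far
#' validation loss without improvement (minimum mode, min-delta 0), or the
#' last epoch if that never happens.
#'
#' @param losses numeric vector of per-epoch validation losses.
#' @param patience allowed number of non-improving epochs.
#' @return list with `stopEpoch` and `bestEpoch`.
#' @export
earlyStoppingEpoch <- function(losses, patience) {
  best <- Inf; bestEpoch <- 0L
  for (e in seq_along(losses)) {
    if (losses[e] < best) {
      best <- losses[e]
      bestEpoch <- e
    } else if (e - bestEpoch >= patience) {
      return(list(stopEpoch = e, bestEpoch = bestEpoch))
    }
  }
  list(stopEpoch = length(losses), bestEpoch = bestEpoch)
}

# mean validation loss and Dice(WT) of hard predictions over a dataset
.evalSet <- function(model, set, epsilon = 1e-6) {
  tot <- 0; dw <- 0
  for (it in set) {
    pm <- forwardPredict(model, it$slice,
                         featureStacks = if (is.null(it$features)) NULL
                                         else list(it$features))
    lv <- combinedLoss(pm, it$mask, epsilon)
    tot <- tot + lv@total
    m <- segmentationMetrics(confusionCounts(regionBinarize(pm@labels, "WT"),
                                             regionBinarize(it$mask, "WT")))
    dw <- dw + m["dice"]
  }
  c(loss = tot / length(set), dice = unname(dw) / length(set))
}

#' Train a model by minibatch SGD with momentum and early stopping
#'
#' Optimizes the combined cross-entropy + soft-Dice objective with
#' stochastic gradient descent (momentum and weight decay per the training
#' config), evaluating the validation loss each epoch, stopping early when
#' it fails to improve for `patience` consecutive epochs, and restoring the
#' best-validation weights. Deterministic given the config seed on a single
#' CPU thread.
#'
#' Each dataset item is a `list(slice = MultiModalSlice, mask =
#' SegmentationMask, features = FeatureStack or NULL)`; `features` is
#' required when the model fuses handcrafted channels. If `valSet` is
#' `NULL`, a seeded 10% of the training items (at least one) is held out for
#' early stopping.
#'
#' @param model a [HybridModel-class].
#' @param trainSet,valSet lists of dataset items.
#' @param config a [trainConfig()].
#' @param augment optional [augmentationConfig()] applied per (epoch,
#'   item) draw; `NULL` disables augmentation.
#' @param featureFn optional `function(slice) -> FeatureStack` used to
#'   recompute handcrafted features on each augmented slice so the fused
#'   channels stay aligned with the warped geometry; when `NULL`, the
#'   stored feature stacks are used as-is.
#' @param verbose print per-epoch progress.
#' @return `list(model = trained model, history = TrainHistory)`. If the
#'   loss turns non-finite, training aborts with a warning ("diverged") and
#'   the history collected so far is returned.
#' @export
trainModel <- function(model, trainSet, valSet = NULL,
                       config = trainConfig(), augment = NULL,
                       featureFn = NULL, verbose = FALSE) {
  if (length(trainSet) == 0L) stop("no data")
  if (is.null(valSet)) {
    nVal <- max(1L, round(0.1 * length(trainSet)))
    idx <- .withSeed(.deriveSeed(config@seed, 777L),
                     sample(length(trainSet), nVal))
    valSet <- trainSet[idx]
    trainSet <- trainSet[-idx]
    if (length(trainSet) == 0L) stop("no data")
  }
  needFS <- model@config@fusion != "none"
  if (needFS && is.null(trainSet[[1]]$features)) stop("fusion input required")

  vel <- lapply(model@params, function(p) array(0, dim = dim(p) %||% length(p)))
  histEpoch <- integer(0); histTrain <- numeric(0)
  histVal <- numeric(0); histDice <- numeric(0)
  bestLoss <- Inf; bestEpoch <- 0L; bestParams <- model@params
  stoppedAt <- 0L
  n <- length(trainSet)
  for (epoch in seq_len(config@epochs)) {
    ord <- .withSeed(.deriveSeed(config@seed, epoch), sample(n))
    epochLoss <- 0; nBatches <- 0L
    for (b0 in seq(1L, n, by = config@batchSize)) {
      ids <- ord[b0:min(b0 + config@batchSize - 1L, n)]
      items <- trainSet[ids]
      if (!is.null(augment)) {
        items <- lapply(seq_along(items), function(j) {
          it <- items[[j]]
          aug <- augmentPair(it$slice, it$mask, augment,
                             seed = .deriveSeed(config@seed,
                                                epoch * 100000L + ids[j]))
          feat <- if (is.null(featureFn)) it$features else featureFn(aug$slice)
          list(slice = aug$slice, mask = aug$mask, features = feat)
        })
      }
      X <- .sliceBatch(lapply(items, `[[`, "slice"))
      FS <- if (needFS) .stackBatch(lapply(items, `[[`, "features")) else NULL
      d <- dim(X)
      labs <- array(0L, dim = c(d[1], d[2], length(items)))
      for (j in seq_along(items))
        labs[, , j] <- maskLabels(items[[j]]$mask)
      fw <- .forwardModel(model, X, FS, wantCache = TRUE)
      lg <- .lossAndGrad(fw$probs, labs)
      if (!is.finite(lg$total)) {
        warning("diverged: non-finite training loss")
        history <- new("TrainHistory", epoch = histEpoch,
                       trainLoss = histTrain, valLoss = histVal,
                       valDice = histDice, stoppedAt = epoch,
                       bestEpoch = bestEpoch,
                       config = .echoConfig(config))
        return(list(model = model, history = history))
      }
      grads <- .backwardModel(model, fw$cache, lg$dLogits)
      for (nm in names(model@params)) {
        g <- grads[[nm]] + config@weightDecay * model@params[[nm]]
        vel[[nm]] <- config@momentum * vel[[nm]] - config@learningRate * g
        model@params[[nm]] <- model@params[[nm]] + vel[[nm]]
      }
      epochLoss <- epochLoss + lg$total
      nBatches <- nBatches + 1L
    }
    ev <- .evalSet(model, valSet)
    histEpoch <- c(histEpoch, epoch)
    histTrain <- c(histTrain, epochLoss / nBatches)
    histVal <- c(histVal, ev["loss"])
    histDice <- c(histDice, ev["dice"])
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f dice(WT) %.4f",
                      epoch, epochLoss / nBatches, ev["loss"], ev["dice"]))
    if (ev["loss"] < bestLoss) {
      bestLoss <- ev["loss"]
      bestEpoch <- epoch
      bestParams <- model@params
    } else if (epoch - bestEpoch >= config@patience) {
      stoppedAt <- epoch
      break
    }
    stoppedAt <- epoch
  }
  model@params <- bestParams
  history <- new("TrainHistory", epoch = histEpoch, trainLoss = histTrain,
                 valLoss = unname(histVal), valDice = unname(histDice),
                 stoppedAt = stoppedAt, bestEpoch = bestEpoch,
                 config = .echoConfig(config))
  list(model = model, history = history)
}

.echoConfig <- function(config) {
  list(momentum = config@momentum, learningRate = config@learningRate,
       weightDecay = config@weightDecay, batchSize = config@batchSize,
       epochs = config@epochs, patience = config@patience,
       seed = config@seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fine-tune a trained model after handcrafted-feature integration
#'
#' Runs the same training loop with the learning rate reduced by a factor of
#' 10 and the epoch count capped at 50, the schedule used to adapt the
#' network after the handcrafted channels are fused in without drastically
#' changing the learned features.
#'
#' @inheritParams trainModel
#' @param baseConfig the [trainConfig()] used for initial training.
#' @return as [trainModel()]; the history's config echo records the
#'   reduced learning rate.
#' @export
finetuneModel <- function(model, trainSet, valSet = NULL,
                          baseConfig = trainConfig(), augment = NULL,
                          featureFn = NULL, verbose = FALSE) {
  ftConfig <- trainConfig(momentum = baseConfig@momentum,
                          learningRate = baseConfig@learningRate / 10,
                          weightDecay = baseConfig@weightDecay,
                          batchSize = baseConfig@batchSize,
                          epochs = min(baseConfig@epochs, 50L),
                          patience = baseConfig@patience,
                          seed = baseConfig@seed)
  trainModel(model, trainSet, valSet, ftConfig, augment, featureFn, verbose)
}
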