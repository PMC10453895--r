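# reference simulation of the early-stopping rule
stopOracle <- function(losses, patience) {
  best <- Inf; bestE <- 0L
  for (e in seq_along(losses)) {
    if (losses[e] < best) { best <- losses[e]; bestE <- e }
    else if (e - bestE >= patience) return(list(stopEpoch = e, bestEpoch = bestE))
  }
  list(stopEpoch = length(losses), bestEpoch = bestE)
}

makeTrainItems <- function(n = 8L, side = 16L, seed = 2L, features = FALSE) {
  sp <- phantomSpec(imageSize = side, tumorRadiusRange = c(2, 3.5),
                    seed = seed)
  ds <- generatePhantomDataset(sp, n, seed = seed)
  if (features)
    ds <- lapply(ds, function(p) {
      p$features <- extractFeatures(p$slice, features = "hog",
                                    hogParams = hogParams(cellSize = 4L))
      p
    })
  ds
}

test_that("the 70:30 split reproduces the 200/85 convention and partitions", {
  sp <- splitDataset(sprintf("case%03d", 1:285), 0.70, seed = 1L)
  expect_length(sp$train, 200L)
  expect_length(sp$test, 85L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), sprintf("case%03d", 1:285))

  sp2 <- splitDataset(sprintf("case%03d", 1:285), 0.70, seed = 1L)
  expect_identical(sp, sp2)

  set.seed(51)
  for (rep in 1:100) {
    n <- sample(3:400, 1)
    frac <- runif(1, 0.2, 0.9)
    ids <- seq_len(n)
    s <- splitDataset(ids, frac, seed = rep)
    expect_setequal(c(s$train, s$test), ids)
    expect_length(intersect(s$train, s$test), 0L)
    expect_length(s$train, round(frac * n))
  }
  expect_error(splitDataset(c(1, 1, 2), 0.5), "non-unique cases")
})

test_that("the early-stopping rule matches a reference simulation", {
  st <- earlyStoppingEpoch(c(1.0, 0.9, 0.9, 0.9, 0.9), patience = 2L)
  expect_equal(st$stopEpoch, 4L)     # two non-improving epochs past the best
  expect_equal(st$bestEpoch, 2L)
  set.seed(52)
  for (rep in 1:200) {
    losses <- round(runif(sample(1:20, 1), 0, 2), 2)
    patience <- sample(1:5, 1)
    expect_identical(earlyStoppingEpoch(losses, patience),
                     stopOracle(losses, patience))
  }
})

test_that("zero allowed epochs return the model unchanged with empty history", {
  items <- makeTrainItems(4L)
  m <- buildCNN(tinyModelConfig(), seed = 3L)
  out <- trainModel(m, items, config = trainConfig(epochs = 0L))
  expect_identical(out$model@params, m@params)
  expect_length(out$history@epoch, 0L)
  expect_error(trainModel(m, list(), config = trainConfig(epochs = 1L)),
               "no data")
})

test_that("one SGD step with vanishing learning rate leaves weights unchanged", {
  items <- makeTrainItems(2L)
  m <- buildCNN(tinyModelConfig(), seed = 3L)
  out <- trainModel(m, items, valSet = items,
                    config = trainConfig(epochs = 1L, batchSize = 2L,
                                         learningRate = 1e-300,
                                         weightDecay = 0))
  # best-weight restoration returns the epoch-1 weights; with lr -> 0 these
  # equal the initial weights to numerical precision
  for (nm in names(m@params))
    expect_lt(max(abs(out$model@params[[nm]] - m@params[[nm]])), 1e-12)
})

test_that("training reduces the loss on phantoms for most early transitions", {
  drops <- vapply(1:3, function(s) {
    items <- makeTrainItems(12L, seed = 60L + s)
    m <- buildCNN(tinyModelConfig(), seed = s)
    out <- trainModel(m, items, valSet = items[1:2],
                      config = trainConfig(epochs = 5L, batchSize = 4L,
                                           seed = s))
    tl <- out$history@trainLoss
    sum(diff(tl) <= 0)
  }, numeric(1))
  expect_gte(median(drops), 4)
})

test_that("training histories satisfy the patience rule against the oracle", {
  items <- makeTrainItems(10L, seed = 70L)
  m <- buildCNN(tinyModelConfig(), seed = 5L)
  out <- trainModel(m, items, valSet = items[1:2],
                    config = trainConfig(epochs = 8L, batchSize = 4L,
                                         patience = 2L))
  h <- out$history
  ref <- stopOracle(h@valLoss, 2L)
  expect_equal(h@stoppedAt, ref$stopEpoch)
  expect_equal(h@bestEpoch, ref$bestEpoch)
  expect_lte(length(h@epoch), 8L)
})

test_that("training is deterministic given the seed", {
  items <- makeTrainItems(6L, seed = 80L)
  m <- buildCNN(tinyModelConfig(), seed = 2L)
  cfg <- trainConfig(epochs = 2L, batchSize = 3L, seed = 4L)
  a <- trainModel(m, items, valSet = items[1:2], config = cfg)
  b <- trainModel(m, items, valSet = items[1:2], config = cfg)
  expect_identical(a$model@params, b$model@params)
  expect_identical(a$history@trainLoss, b$history@trainLoss)
})

test_that("fine-tuning runs at a tenth of the learning rate, capped at 50 epochs", {
  items <- makeTrainItems(4L, seed = 90L)
  m <- buildCNN(tinyModelConfig(), seed = 2L)
  out <- finetuneModel(m, items, valSet = items[1:2],
                       baseConfig = trainConfig(epochs = 1L,
                                                learningRate = 0.0010))
  expect_equal(out$history@config$learningRate, 0.0001)
  expect_equal(out$history@config$epochs, 1L)
  # a 100-epoch base config caps fine-tuning at 50 (recorded in the echo)
  ft <- finetuneModel(m, items, valSet = items[1:2],
                      baseConfig = trainConfig(epochs = 100L, patience = 1L))
  expect_equal(ft$history@config$epochs, 50L)
  expect_lte(length(ft$history@epoch), 50L)
  # zero allowed epochs leave the weights bit-exact
  ft0 <- finetuneModel(m, items, valSet = items[1:2],
                       baseConfig = trainConfig(epochs = 0L))
  expect_length(ft0$history@epoch, 0L)
  expect_identical(ft0$model@params, m@params)
})

test_that("hybrid training demands feature stacks", {
  items <- makeTrainItems(4L, seed = 91L)
  hyb <- buildHybrid(tinyModelConfig(fusion = "decision_level", k = 9L))
  expect_error(trainModel(hyb, items, valSet = items[1:2],
                          config = trainConfig(epochs = 1L)),
               "fusion input required")
  withFS <- makeTrainItems(4L, seed = 91L, features = TRUE)
  k <- nChannels(withFS[[1]]$features)
  hyb2 <- buildHybrid(tinyModelConfig(fusion = "decision_level", k = k))
  out <- trainModel(hyb2, withFS, valSet = withFS[1:2],
                    config = trainConfig(epochs = 1L, batchSize = 2L))
  expect_length(out$history@epoch, 1L)

  # under augmentation, features can be recomputed on each warped slice
  calls <- 0L
  fn <- function(slice) {
    calls <<- calls + 1L
    extractFeatures(slice, features = "hog",
                    hogParams = hogParams(cellSize = 4L))
  }
  out2 <- trainModel(hyb2, withFS, valSet = withFS[1:2],
                     config = trainConfig(epochs = 1L, batchSize = 2L),
                     augment = augmentationConfig(elasticAlpha = 0),
                     featureFn = fn)
  expect_length(out2$history@epoch, 1L)
  expect_gt(calls, 0L)
})
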