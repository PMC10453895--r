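test_that("the baseline CNN maps input to congruent softmax maps", {
  cfg <- hybridModelConfig(inputSize = 256L)
  expect_equal(cfg@encoderChannels, c(64L, 128L, 256L, 512L))
  # reduced config keeps the contract at desk scale
  small <- hybridModelConfig(inputSize = 64L,
                             encoderChannels = c(8L, 16L, 32L, 64L))
  m <- buildCNN(small, seed = 2L)
  set.seed(2)
  X <- array(runif(64 * 64 * 1 * 4), dim = c(64, 64, 1, 4))
  probs <- hybridSeg:::.forwardModel(m, X)$probs
  expect_equal(dim(probs), c(64L, 64L, 1L, 4L))
  expect_lt(max(abs(apply(probs, c(1, 2, 3), sum) - 1)), 1e-5)
  expect_true(all(probs >= 0))

  # construction is deterministic: identical builds, identical parameters
  m2 <- buildCNN(small, seed = 2L)
  expect_identical(m@params, m2@params)
  np <- sum(vapply(m@params, length, integer(1)))
  expect_equal(np, sum(vapply(m2@params, length, integer(1))))

  expect_error(hybridModelConfig(inputSize = 100L,
                                 encoderChannels = c(8L, 16L, 32L, 64L)),
               "invalid input size")
})

test_that("encoder channel widths and deepest width match the architecture table", {
  m <- buildCNN(hybridModelConfig(inputSize = 64L), seed = 1L)
  tb <- modelSummary(m)
  encRows <- tb[grepl("^enc", tb$layer), ]
  expect_equal(encRows$channels, c(64L, 128L, 256L, 512L))
  expect_equal(max(tb$channels), 512L)
  expect_equal(tb$channels[tb$layer == "out (conv 1x1 + softmax)"], 4L)
  # summary is exportable as JSON
  f <- withr::local_tempfile(fileext = ".json")
  modelSummary(m, f)
  js <- jsonlite::fromJSON(f)
  expect_equal(nrow(js), nrow(tb))
})

test_that("hybrid variants size their fusion convolutions by concatenation arithmetic", {
  base <- hybridModelConfig(inputSize = 64L)
  ic <- buildHybrid(hybridModelConfig(inputSize = 64L,
                                      fusion = "input_channel",
                                      handcraftedChannels = 9L))
  expect_equal(dim(ic@params$enc1_W)[3], 13L)            # 4 + 9
  dl <- buildHybrid(hybridModelConfig(inputSize = 64L,
                                      fusion = "decision_level",
                                      handcraftedChannels = 9L))
  expect_equal(dim(dl@params$out_W)[3], 73L)             # 64 + 9
  fm <- buildHybrid(hybridModelConfig(inputSize = 64L,
                                      fusion = "feature_map",
                                      handcraftedChannels = 9L,
                                      fusionDepth = 2L))
  expect_equal(dim(fm@params$enc3_W)[3], 128L + 9L)
  expect_error(buildHybrid(hybridModelConfig(inputSize = 64L,
                                             fusion = "decision_level",
                                             handcraftedChannels = 0L), k = 0L),
               "no handcrafted channels")
  expect_error(hybridModelConfig(inputSize = 64L, fusion = "feature_map",
                                 handcraftedChannels = 2L, fusionDepth = 9L),
               "bad fusion point")
})

test_that("output shape follows input spatial shape for divisible sizes", {
  for (sz in c(16L, 32L, 48L)) {
    m <- buildCNN(hybridModelConfig(inputSize = sz,
                                    encoderChannels = c(3L, 4L)), seed = 1L)
    X <- array(runif(sz * sz * 2 * 4), dim = c(sz, sz, 2, 4))
    probs <- hybridSeg:::.forwardModel(m, X)$probs
    expect_equal(dim(probs), c(sz, sz, 2L, 4L))
  }
})

test_that("each hybrid variant with zeroed fusion weights reproduces the baseline", {
  for (fu in c("input_channel", "feature_map", "decision_level")) {
    base <- buildCNN(tinyModelConfig(), seed = 9L)
    hyb <- buildHybrid(tinyModelConfig(fusion = fu, k = 6L, fusionDepth = 2L),
                       seed = 9L)
    hyb0 <- zeroFusionWeights(hyb)
    b <- randomBatch(h = 16L, seed = 4L)
    FS <- array(runif(16 * 16 * 1 * 6), dim = c(16, 16, 1, 6))
    pb <- hybridSeg:::.forwardModel(base, b$X)$probs
    ph <- hybridSeg:::.forwardModel(hyb0, b$X, FS)$probs
    expect_identical(pb, ph)
    # with nonzero fusion weights the outputs must differ
    ph1 <- hybridSeg:::.forwardModel(hyb, b$X, FS)$probs
    expect_false(identical(pb, ph1))
  }
})

test_that("a zero feature stack leaves decision-level output equal to baseline", {
  base <- buildCNN(tinyModelConfig(), seed = 9L)
  hyb <- buildHybrid(tinyModelConfig(fusion = "decision_level", k = 6L),
                     seed = 9L)
  b <- randomBatch(h = 16L, seed = 4L)
  FS0 <- array(0, dim = c(16, 16, 1, 6))
  pb <- hybridSeg:::.forwardModel(base, b$X)$probs
  ph <- hybridSeg:::.forwardModel(hyb, b$X, FS0)$probs
  expect_identical(pb, ph)   # zero inputs to the extra classifier weights
})

test_that("analytic gradients match numeric differentiation", {
  m <- buildCNN(tinyModelConfig(), seed = 7L)
  b <- randomBatch(h = 16L, n = 2L, seed = 3L)
  fw <- hybridSeg:::.forwardModel(m, b$X, wantCache = TRUE)
  lg <- hybridSeg:::.lossAndGrad(fw$probs, b$labs)
  gr <- hybridSeg:::.backwardModel(m, fw$cache, lg$dLogits)
  lossOf <- function(mm)
    hybridSeg:::.lossAndGrad(hybridSeg:::.forwardModel(mm, b$X)$probs,
                             b$labs)$total
  eps <- 1e-5
  set.seed(8)
  for (nm in names(m@params)) {
    i <- sample(length(m@params[[nm]]), 1)
    up <- m; up@params[[nm]][i] <- up@params[[nm]][i] + eps
    dn <- m; dn@params[[nm]][i] <- dn@params[[nm]][i] - eps
    num <- (lossOf(up) - lossOf(dn)) / (2 * eps)
    expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("forwardPredict returns normalized, deterministic prediction maps", {
  pair <- makeTestSlicePair(side = 16L)
  m <- buildCNN(tinyModelConfig(), seed = 5L)
  pm <- forwardPredict(m, pair$slice)
  expect_s4_class(pm, "PredictionMap")
  sums <- apply(pm@probabilities, c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_true(all(pm@labels %in% 0:3))
  pm2 <- forwardPredict(m, pair$slice)
  expect_identical(pm@probabilities, pm2@probabilities)

  # argmax ties break toward the smaller class index
  tied <- matrix(hybridSeg:::.softmaxC(array(0, c(2, 2, 1, 4)))[, , 1, ],
                 4, 4)
  expect_true(all(abs(tied - 0.25) < 1e-12))
  P <- array(0.25, dim = c(2, 2, 4))
  M <- matrix(P, 4, 4)
  expect_true(all(max.col(M, ties.method = "first") == 1L))

  hyb <- buildHybrid(tinyModelConfig(fusion = "decision_level", k = 2L))
  expect_error(forwardPredict(hyb, pair$slice), "fusion input required")
})

test_that("model checkpoints round-trip through save/load", {
  m <- buildCNN(tinyModelConfig(), seed = 5L)
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_identical(m@params, m2@params)
  b <- randomBatch(h = 16L)
  expect_identical(hybridSeg:::.forwardModel(m, b$X)$probs,
                   hybridSeg:::.forwardModel(m2, b$X)$probs)
})
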