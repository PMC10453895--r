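# prediction helpers: one-hot and uniform probability maps
oneHotProbs <- function(labels, nClasses = 4L) {
  d <- dim(labels)
  P <- array(0, dim = c(d[1], d[2], nClasses))
  for (cl in 0:(nClasses - 1L)) P[, , cl + 1L] <- (labels == cl) * 1
  P
}

test_that("cross-entropy matches its defining formula and clipping rule", {
  lab <- matrix(sample(0:3, 16, TRUE), 4, 4)
  expect_equal(crossEntropyLoss(oneHotProbs(lab), lab), 0)
  uni <- array(0.25, dim = c(4, 4, 4))
  expect_equal(crossEntropyLoss(uni, lab), log(4), tolerance = 1e-9)
  # zero probability on the true class hits the 1e-7 clip
  wrong <- oneHotProbs((lab + 1L) %% 4L)
  expect_equal(crossEntropyLoss(wrong, lab), -log(1e-7), tolerance = 1e-6)
  bad <- lab; bad[1, 1] <- 7L
  expect_error(crossEntropyLoss(uni, bad), "invalid target")
})

test_that("soft Dice loss evaluates its ratio exactly", {
  expect_equal(diceLoss(c(1, 0, 0, 0), c(1, 1, 0, 0)), 1 / 3,
               tolerance = 1e-3)
  expect_lt(diceLoss(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1e-6)
  expect_gt(diceLoss(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1 - 1e-3)
  expect_error(diceLoss(c(1), c(1), epsilon = 0), "invalid smoothing")

  lab <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  expect_lt(diceLoss(oneHotProbs(lab), lab), 1e-6)
})

test_that("combined loss is the sum of its terms and vanishes at the truth", {
  lab <- matrix(sample(0:3, 64, TRUE), 8, 8)
  lv <- combinedLoss(oneHotProbs(lab), lab)
  expect_lt(lv@total, 1e-3)
  expect_equal(lv@total, lv@crossEntropyTerm + lv@diceTerm)
  set.seed(41)
  for (rep in 1:10) {
    raw <- array(runif(8 * 8 * 4), dim = c(8, 8, 4))
    s <- apply(raw, c(1, 2), sum)
    probs <- raw / array(rep(s, 4), dim = dim(raw))
    lv <- combinedLoss(probs, lab)
    expect_equal(lv@total, lv@crossEntropyTerm + lv@diceTerm)
    expect_gte(lv@diceTerm, 0)
  }
})

test_that("uniform prediction on a half-foreground mask matches the closed form", {
  lab <- matrix(0L, 4, 4)
  lab[, 3:4] <- 1L                      # half the pixels are class 1
  uni <- array(0.25, dim = c(4, 4, 4))
  lv <- combinedLoss(uni, lab)
  expect_equal(lv@crossEntropyTerm, log(4), tolerance = 1e-9)
  # direct summation oracle for the dice term, per foreground class
  eps <- 1e-6
  ratios <- vapply(1:3, function(cl) {
    y <- as.numeric(lab == cl)
    p <- rep(0.25, 16)
    (2 * sum(y * p) + eps) / (sum(y) + sum(p) + eps)
  }, numeric(1))
  expect_equal(lv@diceTerm, 1 - mean(ratios), tolerance = 1e-12)
})

test_that("region binarization follows the WT/TC/ET label unions", {
  m <- matrix(c(0L, 2L, 1L, 3L), 2, 2)   # [[0,1],[2,3]] in row terms
  expect_equal(regionBinarize(m, "WT"), matrix(c(0L, 1L, 1L, 1L), 2, 2))
  expect_equal(regionBinarize(m, "TC"), matrix(c(0L, 1L, 0L, 1L), 2, 2))
  expect_equal(regionBinarize(m, "ET"), matrix(c(0L, 0L, 0L, 1L), 2, 2))
  z <- matrix(0L, 3, 3)
  for (rg in c("WT", "TC", "ET"))
    expect_true(all(regionBinarize(z, rg) == 0L))
  expect_error(regionBinarize(m, "XX"), "invalid region")
})

test_that("confusion counts tabulate pixels and match a loop oracle", {
  cc <- confusionCounts(c(1, 0, 1, 1), c(1, 1, 0, 1))
  expect_equal(c(cc@tp, cc@fn, cc@fp, cc@tn), c(2, 1, 1, 0))
  ident <- confusionCounts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(c(ident@fp, ident@fn), c(0, 0))
  set.seed(42)
  for (rep in 1:20) {
    a <- matrix(rbinom(256, 1, 0.4), 16, 16)
    b <- matrix(rbinom(256, 1, 0.4), 16, 16)
    got <- confusionCounts(a, b)
    tp <- tn <- fp <- fn <- 0
    for (i in 1:16) for (j in 1:16) {
      if (a[i, j] == 1 && b[i, j] == 1) tp <- tp + 1
      else if (a[i, j] == 0 && b[i, j] == 0) tn <- tn + 1
      else if (a[i, j] == 1) fp <- fp + 1
      else fn <- fn + 1
    }
    expect_equal(c(got@tp, got@tn, got@fp, got@fn), c(tp, tn, fp, fn))
    expect_equal(got@tp + got@tn + got@fp + got@fn, 256)
  }
  expect_error(confusionCounts(matrix(0, 2, 2), matrix(0, 3, 3)),
               "unaligned masks")
})

test_that("the four metrics evaluate their formulas and conventions", {
  cc <- new("ConfusionCounts", tp = 8, tn = 80, fp = 2, fn = 2)
  m <- segmentationMetrics(cc)
  expect_equal(unname(m["accuracy"]), 88 / 92)
  expect_equal(unname(m["dice"]), 0.8)
  expect_equal(unname(m["sensitivity"]), 0.8)
  expect_equal(unname(m["specificity"]), 80 / 82)

  perfect <- segmentationMetrics(new("ConfusionCounts", tp = 5, tn = 5,
                                     fp = 0, fn = 0))
  expect_true(all(perfect == 1))

  # empty ground-truth region predicted empty scores 1.0
  empty <- segmentationMetrics(new("ConfusionCounts", tp = 0, tn = 9,
                                   fp = 0, fn = 0))
  expect_equal(unname(empty["dice"]), 1)
  expect_equal(unname(empty["sensitivity"]), 1)
  # ... predicted nonempty scores 0
  spill <- segmentationMetrics(new("ConfusionCounts", tp = 0, tn = 8,
                                   fp = 1, fn = 0))
  expect_equal(unname(spill["dice"]), 0)
  expect_equal(unname(spill["sensitivity"]), 0)
  expect_error(segmentationMetrics(new("ConfusionCounts", tp = -1, tn = 0,
                                       fp = 0, fn = 0)))
})

test_that("metrics stay in [0,1] and respect the swap symmetries", {
  set.seed(43)
  for (rep in 1:50) {
    cc <- new("ConfusionCounts", tp = rpois(1, 5), tn = rpois(1, 5),
              fp = rpois(1, 5), fn = rpois(1, 5))
    m <- segmentationMetrics(cc)
    expect_true(all(m >= 0 & m <= 1))
    # accuracy is symmetric under pred/truth swap (TP<->TP, FP<->FN)
    sw <- segmentationMetrics(new("ConfusionCounts", tp = cc@tp, tn = cc@tn,
                                  fp = cc@fn, fn = cc@fp))
    expect_equal(m["accuracy"], sw["accuracy"])
    # class inversion of both masks swaps sensitivity and specificity
    inv <- segmentationMetrics(new("ConfusionCounts", tp = cc@tn, tn = cc@tp,
                                   fp = cc@fn, fn = cc@fp))
    expect_equal(unname(m["sensitivity"]), unname(inv["specificity"]))
    expect_equal(unname(m["specificity"]), unname(inv["sensitivity"]))
  }
})

test_that("hard-prediction Dice agrees with soft Dice of the one-hot map", {
  set.seed(44)
  for (rep in 1:100) {
    truth <- matrix(sample(0:1, 64, TRUE), 8, 8)
    pred <- matrix(sample(0:1, 64, TRUE), 8, 8)
    cc <- confusionCounts(pred, truth)
    hard <- unname(segmentationMetrics(cc)["dice"])
    soft <- 1 - diceLoss(as.numeric(pred), as.numeric(truth),
                         epsilon = 1e-12)
    expect_equal(hard, soft, tolerance = 1e-6)
  }
})

test_that("dataset evaluation averages per-case metrics per region", {
  lab1 <- matrix(sample(0:3, 64, TRUE), 8, 8)
  perfect <- evaluateDataset(list(lab1), list(lab1))
  expect_true(all(unlist(perfect@summary[, -1]) == 1))

  set.seed(45)
  preds <- lapply(1:6, function(i) matrix(sample(0:3, 64, TRUE), 8, 8))
  truths <- lapply(1:6, function(i) matrix(sample(0:3, 64, TRUE), 8, 8))
  rep6 <- evaluateDataset(preds, truths)
  # oracle: recompute the aggregation from the per-case table
  for (rg in c("WT", "TC", "ET")) {
    sub <- rep6@perCase[rep6@perCase$region == rg, ]
    expect_equal(rep6@summary$dice[rep6@summary$region == rg],
                 mean(sub$dice))
    # and each per-case value against direct computation
    for (i in 1:6) {
      d <- segmentationMetrics(confusionCounts(
        regionBinarize(preds[[i]], rg), regionBinarize(truths[[i]], rg)))
      expect_equal(sub$dice[sub$case == i], unname(d["dice"]))
    }
  }
  expect_error(evaluateDataset(list(), list()), "nothing to evaluate")

  # two cases with dice 0.8 and 1.0 average to 0.9
  t1 <- matrix(0L, 4, 4); t1[1:2, 1] <- 1L
  p1 <- matrix(0L, 4, 4); p1[1:3, 1] <- 1L   # dice 2*2/(2*2+1) = 0.8
  r <- evaluateDataset(list(p1, t1), list(t1, t1))
  expect_equal(r@summary$dice[r@summary$region == "WT"], 0.9)

  # JSON serialization has the {region: {metric: value}} schema
  js <- jsonlite::fromJSON(metricsJSON(r))
  expect_named(js, c("WT", "TC", "ET"))
  expect_named(js$WT, c("accuracy", "dice", "sensitivity", "specificity"))
})
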