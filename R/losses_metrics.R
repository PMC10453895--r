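#' @include AllClasses.R
NULL

# coerce (probabilities, target) to a (nPixels x nClasses) matrix and an
# integer label vector in 0..nClasses-1
.probTarget <- function(probabilities, target) {
  if (is(probabilities, "PredictionMap"))
    probabilities <- probabilities@probabilities
  if (is(target, "SegmentationMask")) target <- maskLabels(target)
  d <- dim(probabilities)
  if (length(d) != 3L) stop("probabilities must be (height, width, nClasses)")
  if (!all(dim(target) == d[1:2])) stop("unaligned masks")
  P <- matrix(probabilities, d[1] * d[2], d[3])
  y <- as.integer(as.vector(target))
  if (any(y < 0L) || any(y >= d[3])) stop("invalid target: label outside class range")
  list(P = P, y = y, nClasses = d[3])
}

#' Cross-entropy loss
#'
#' Mean over pixels of `-log p(true class)`, with the probability clipped to
#' \[1e-7, 1\] so that a zero predicted probability yields a large finite
#' penalty rather than infinity.
#'
#' @param probabilities a [PredictionMap-class] or (height, width,
#'   nClasses) probability array.
#' @param target a [SegmentationMask-class] or integer label matrix.
#' @return nonnegative scalar.
#' @export
crossEntropyLoss <- function(probabilities, target) {
  pt <- .probTarget(probabilities, target)
  p <- pt$P[cbind(seq_along(pt$y), pt$y + 1L)]
  mean(-log(pmin(pmax(p, 1e-7), 1)))
}

#' Soft Dice loss
#'
#' `1 - mean over foreground classes of (2 sum(y p) + eps) /
#' (sum(y) + sum(p) + eps)`, where `y` is the one-hot target and `p` the
#' predicted probability of the class. Background (class 0) is excluded from
#' the mean by default. Plain numeric vectors are treated as a single
#' class's pixels, which makes the binary soft Dice directly accessible.
#'
#' @param probabilities prediction as in [crossEntropyLoss()], or a numeric
#'   vector/matrix of per-pixel probabilities for one class.
#' @param target matching target (one-hot labels for the vector form).
#' @param epsilon smoothing constant (> 0).
#' @param classes integer vector of class labels averaged over (default all
#'   foreground classes).
#' @return scalar in \[0, 1\].
#' @export
diceLoss <- function(probabilities, target, epsilon = 1e-6, classes = NULL) {
  if (epsilon <= 0) stop("invalid smoothing: epsilon must be > 0")
  if (!is(probabilities, "PredictionMap") &&
      length(dim(probabilities)) != 3L) {
    p <- as.numeric(probabilities); y <- as.numeric(target)
    if (length(p) != length(y)) stop("unaligned masks")
    return(1 - (2 * sum(y * p) + epsilon) / (sum(y) + sum(p) + epsilon))
  }
  pt <- .probTarget(probabilities, target)
  if (is.null(classes)) classes <- seq_len(pt$nClasses - 1L)
  ratios <- vapply(classes, function(cl) {
    y <- as.numeric(pt$y == cl)
    p <- pt$P[, cl + 1L]
    (2 * sum(y * p) + epsilon) / (sum(y) + sum(p) + epsilon)
  }, numeric(1))
  1 - mean(ratios)
}

#' Combined cross-entropy + soft-Dice training objective
#'
#' `total = crossEntropy + (1 - softDice)`; both terms vanish as the
#' prediction approaches the ground truth, so a perfect prediction minimizes
#' the objective.
#'
#' @inheritParams diceLoss
#' @return a [LossValue-class] with slots total, crossEntropyTerm,
#'   diceTerm.
#' @export
combinedLoss <- function(probabilities, target, epsilon = 1e-6) {
  ce <- crossEntropyLoss(probabilities, target)
  dl <- diceLoss(probabilities, target, epsilon)
  new("LossValue", total = ce + dl, crossEntropyTerm = ce, diceTerm = dl)
}

#' Binarize a mask to a BraTS evaluation region
#'
#' Whole tumor (WT) is the union of labels {1, 2, 3}, tumor core (TC) is
#' {2, 3}, enhancing tumor (ET) is {3}.
#'
#' @param mask a [SegmentationMask-class] or integer label array.
#' @param region one of "WT", "TC", "ET".
#' @return binary integer array of the mask's shape.
#' @export
regionBinarize <- function(mask, region) {
  lab <- if (is(mask, "SegmentationMask")) maskLabels(mask) else mask
  members <- switch(region,
                    WT = c(1L, 2L, 3L),
                    TC = c(2L, 3L),
                    ET = 3L,
                    stop("invalid region: ", region))
  out <- array(0L, dim = dim(lab))
  out[lab %in% members] <- 1L
  out
}

#' Pixel confusion counts between two binary masks
#'
#' @param predicted,truth congruent binary (0/1) arrays.
#' @return a [ConfusionCounts-class]; counts sum to the pixel count.
#' @export
confusionCounts <- function(predicted, truth) {
  if (!all(dim(predicted) == dim(truth))) stop("unaligned masks")
  p <- as.logical(predicted); t <- as.logical(truth)
  new("ConfusionCounts",
      tp = sum(p & t), tn = sum(!p & !t),
      fp = sum(p & !t), fn = sum(!p & t))
}

#' The four segmentation metrics from confusion counts
#'
#' accuracy = (TP+TN)/(TP+TN+FP+FN), dice = 2TP/(2TP+FP+FN),
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP). Empty-denominator
#' convention (BraTS style): a region empty in the ground truth and predicted
#' empty scores 1.0 for the affected metric, otherwise 0.0.
#'
#' @param counts a [ConfusionCounts-class].
#' @return named numeric: accuracy, dice, sensitivity, specificity, all in
#'   \[0, 1\].
#' @examples
#' segmentationMetrics(new("ConfusionCounts", tp = 8, tn = 80, fp = 2, fn = 2))
#' @export
segmentationMetrics <- function(counts) {
  if (!is(counts, "ConfusionCounts")) stop("invalid counts")
  validObject(counts)
  tp <- counts@tp; tn <- counts@tn; fp <- counts@fp; fn <- counts@fn
  total <- tp + tn + fp + fn
  safe <- function(num, den, emptyOk) if (den == 0) as.numeric(emptyOk) else num / den
  c(accuracy = safe(tp + tn, total, TRUE),
    dice = safe(2 * tp, 2 * tp + fp + fn, TRUE),
    sensitivity = safe(tp, tp + fn, fp == 0),
    specificity = safe(tn, tn + fp, fn == 0))
}

.REGIONS <- c("WT", "TC", "ET")

#' Evaluate predicted masks against ground truth over a dataset
#'
#' Per case and per region (WT, TC, ET), masks are binarized, confusion
#' counts tabulated and the four metrics computed; the report carries
#' per-case values and their per-region arithmetic means.
#'
#' @param predictions list of predicted masks ([SegmentationMask-class],
#'   [PredictionMap-class] or integer arrays).
#' @param truths list of ground-truth masks, same length.
#' @return a [MetricsReport-class].
#' @export
evaluateDataset <- function(predictions, truths) {
  if (length(predictions) == 0L) stop("nothing to evaluate")
  if (length(predictions) != length(truths))
    stop("unaligned masks: prediction/truth lists differ in length")
  rows <- list()
  for (i in seq_along(predictions)) {
    pred <- predictions[[i]]
    if (is(pred, "PredictionMap")) pred <- pred@labels
    for (rg in .REGIONS) {
      m <- segmentationMetrics(confusionCounts(regionBinarize(pred, rg),
                                               regionBinarize(truths[[i]], rg)))
      rows[[length(rows) + 1L]] <-
        data.frame(case = i, region = rg, accuracy = m["accuracy"],
                   dice = m["dice"], sensitivity = m["sensitivity"],
                   specificity = m["specificity"], row.names = NULL)
    }
  }
  perCase <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(.REGIONS, function(rg) {
    sub <- perCase[perCase$region == rg, ]
    data.frame(region = rg, accuracy = mean(sub$accuracy),
               dice = mean(sub$dice), sensitivity = mean(sub$sensitivity),
               specificity = mean(sub$specificity))
  }))
  new("MetricsReport", summary = summary, perCase = perCase)
}

#' Serialize a metrics report
#'
#' `metricsJSON` returns (and optionally writes) the
#' `{region: {metric: value}}` JSON of the per-region means;
#' `writeMetricsCSV` writes the per-case table.
#'
#' @param report a [MetricsReport-class].
#' @param path optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
metricsJSON <- function(report, path = NULL) {
  lst <- lapply(seq_len(nrow(report@summary)), function(i) {
    as.list(report@summary[i, c("accuracy", "dice", "sensitivity",
                                "specificity")])
  })
  names(lst) <- report@summary$region
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname metricsJSON
#' @export
writeMetricsCSV <- function(report, path) {
  utils::write.csv(report@perCase, path, row.names = FALSE)
  invisible(path)
}
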