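#' @include AllClasses.R
NULL

#' Extract pixel data
#'
#' Accessors for the array payloads of the image containers. `pixelData`
#' returns the channel-major array of a slice or volume, `maskLabels` the
#' integer label grid of a mask, and `stackChannels` the channel array of a
#' feature stack.
#'
#' @param object a `MultiModalSlice`, `MultiModalVolume`, `SegmentationMask`
#'   or `FeatureStack`.
#' @return the underlying array.
#' @export
setGeneric("pixelData", function(object) standardGeneric("pixelData"))

#' @rdname pixelData
#' @export
setGeneric("maskLabels", function(object) standardGeneric("maskLabels"))

#' @rdname pixelData
#' @export
setGeneric("stackChannels", function(object) standardGeneric("stackChannels"))

#' @rdname pixelData
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @export
#' @rdname pixelData
setMethod("pixelData", "MultiModalSlice", function(object) object@pixels)

#' @export
#' @rdname pixelData
setMethod("pixelData", "MultiModalVolume", function(object) object@voxels)

#' @export
#' @rdname pixelData
setMethod("maskLabels", "SegmentationMask", function(object) object@labels)

#' @export
#' @rdname pixelData
setMethod("stackChannels", "FeatureStack", function(object) object@channels)

#' @export
#' @rdname pixelData
setMethod("nChannels", "FeatureStack", function(object) dim(object@channels)[1])

#' @export
#' @rdname pixelData
setMethod("nChannels", "MultiModalSlice", function(object) dim(object@pixels)[1])

setMethod("show", "MultiModalVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("MultiModalVolume: %d slices of %d x %d, modalities %s\n",
              d[2], d[3], d[4], paste(object@modalityOrder, collapse = "/")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "MultiModalSlice", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("MultiModalSlice: %d x %d, 4 modalities, source slice %s\n",
              d[2], d[3],
              ifelse(is.na(object@sourceIndex), "NA", object@sourceIndex)))
})

setMethod("show", "SegmentationMask", function(object) {
  tb <- table(factor(as.vector(object@labels), levels = 0:3))
  cat(sprintf("SegmentationMask %s: labels 0/1/2/3 = %s\n",
              paste(dim(object@labels), collapse = " x "),
              paste(as.integer(tb), collapse = "/")))
})

setMethod("show", "FeatureStack", function(object) {
  d <- dim(object@channels)
  cat(sprintf("FeatureStack: %d channels on a %d x %d grid (%s)\n",
              d[1], d[2], d[3],
              paste(names(object@provenance), collapse = ", ")))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%g TN=%g FP=%g FN=%g\n",
              object@tp, object@tn, object@fp, object@fn))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport (per-case means):\n")
  print(object@summary, row.names = FALSE)
})

setMethod("show", "HybridModelConfig", function(object) {
  cat(sprintf(
    "HybridModelConfig: input %d x %d x %d, encoder %s, %d classes, fusion=%s",
    object@inputSize, object@inputSize, object@inChannels,
    paste(object@encoderChannels, collapse = "-"), object@nClasses,
    object@fusion))
  if (object@fusion != "none")
    cat(sprintf(" (k=%d)", object@handcraftedChannels))
  cat("\n")
})

setMethod("show", "HybridModel", function(object) {
  show(object@config)
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("HybridModel with %d trainable parameters in %d tensors\n",
              np, length(object@params)))
})

setMethod("show", "PredictionMap", function(object) {
  d <- dim(object@probabilities)
  cat(sprintf("PredictionMap: %d x %d, %d classes; predicted label counts: %s\n",
              d[1], d[2], d[3],
              paste(as.integer(table(factor(object@labels, levels = 0:(d[3] - 1)))),
                    collapse = "/")))
})

setMethod("show", "TrainHistory", function(object) {
  cat(sprintf("TrainHistory: %d epochs (stopped at %d, best %d)\n",
              length(object@epoch), object@stoppedAt, object@bestEpoch))
  if (length(object@epoch)) {
    cat(sprintf("  final train loss %.4f, val loss %.4f, val Dice %.4f\n",
                utils::tail(object@trainLoss, 1), utils::tail(object@valLoss, 1),
                utils::tail(object@valDice, 1)))
  }
})

#' Training history as a data.frame
#'
#' @param x a `TrainHistory`.
#' @param row.names,optional,... passed through for generic compatibility.
#' @return data.frame with columns epoch, trainLoss, valLoss, valDice.
#' @export
as.data.frame.TrainHistory <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(epoch = x@epoch, trainLoss = x@trainLoss, valLoss = x@valLoss,
             valDice = x@valDice)
}
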