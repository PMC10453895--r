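#' @import methods
NULL

#' Multi-modal MRI volume
#'
#' A co-registered, skull-stripped multi-modal MRI volume stored channel-major
#' as a 4-D array with dimensions (modality, slice, row, col). The modality
#' order is fixed to (T1, T1c, T2, FLAIR).
#'
#' @slot voxels 4-D numeric array, dim = c(4, nSlices, nRows, nCols).
#' @slot modalityOrder character(4), always c("T1","T1c","T2","FLAIR").
#' @slot voxelSpacing numeric(3), mm per axis; carried through, unused by the
#'   math.
#'
#' @export
setClass("MultiModalVolume",
  representation(voxels = "array", modalityOrder = "character",
                 voxelSpacing = "numeric"),
  prototype(modalityOrder = c("T1", "T1c", "T2", "FLAIR"),
            voxelSpacing = c(1, 1, 1)))

setValidity("MultiModalVolume", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 4L) return("voxels must be a 4-D array (modality, slice, row, col)")
  if (d[1] != 4L) return("exactly 4 modality channels are required")
  if (!identical(object@modalityOrder, c("T1", "T1c", "T2", "FLAIR")))
    return("modalityOrder must be c(\"T1\",\"T1c\",\"T2\",\"FLAIR\")")
  if (length(object@voxelSpacing) != 3L) return("voxelSpacing must have length 3")
  TRUE
})

#' One axial multi-modal slice
#'
#' @slot pixels 3-D numeric array, dim = c(4, height, width), channel-major
#'   in (T1, T1c, T2, FLAIR) order, intensities expected in [0, 1].
#' @slot sourceIndex integer, slice number within the source volume (NA for
#'   synthetic slices).
#'
#' @export
setClass("MultiModalSlice",
  representation(pixels = "array", sourceIndex = "integer"),
  prototype(sourceIndex = NA_integer_))

setValidity("MultiModalSlice", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[1] != 4L)
    return("pixels must be a 3-D array with 4 modality channels first")
  TRUE
})

#' Integer segmentation mask
#'
#' Label grid aligned to a slice (matrix) or a volume (3-D array). Labels are
#' 0 background, 1 edema, 2 tumor core interior, 3 enhancing tumor; the BraTS
#' evaluation regions are unions of these (see [regionBinarize()]).
#'
#' @slot labels integer matrix or 3-D array with values in {0, 1, 2, 3}.
#'
#' @export
setClass("SegmentationMask", representation(labels = "array"))

setValidity("SegmentationMask", function(object) {
  v <- object@labels
  if (!(length(dim(v)) %in% c(2L, 3L))) return("labels must be 2-D or 3-D")
  u <- unique(as.vector(v))
  if (!all(u %in% 0:3)) return("label values must lie in {0,1,2,3}")
  TRUE
})

#' Image-aligned handcrafted feature stack
#'
#' @slot channels 3-D numeric array, dim = c(nChannels, height, width); every
#'   channel finite and aligned to the source image grid.
#' @slot provenance named list; one entry per channel group recording the
#'   descriptor name and its parameters.
#'
#' @export
setClass("FeatureStack",
  representation(channels = "array", provenance = "list"))

setValidity("FeatureStack", function(object) {
  d <- dim(object@channels)
  if (length(d) != 3L) return("channels must be a 3-D array (channel, row, col)")
  if (!all(is.finite(object@channels))) return("all channels must be finite")
  TRUE
})

#' Per-region pixel confusion counts
#'
#' TP/TN/FP/FN pixel counts for one binarized region; the sole input to the
#' four segmentation metrics.
#'
#' @slot tp,tn,fp,fn nonnegative counts.
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", tn = "numeric", fp = "numeric", fn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(v < 0) || any(!is.finite(v))) return("counts must be nonnegative finite")
  TRUE
})

#' Combined loss value
#'
#' @slot total,crossEntropyTerm,diceTerm nonnegative scalars with
#'   total = crossEntropyTerm + diceTerm.
#' @export
setClass("LossValue",
  representation(total = "numeric", crossEntropyTerm = "numeric",
                 diceTerm = "numeric"))

setValidity("LossValue", function(object) {
  if (abs(object@total - (object@crossEntropyTerm + object@diceTerm)) > 1e-9)
    return("total must equal crossEntropyTerm + diceTerm")
  if (object@crossEntropyTerm < 0 || object@diceTerm < -1e-12)
    return("loss terms must be nonnegative")
  TRUE
})

#' Per-region evaluation report
#'
#' @slot summary data.frame with one row per region (WT, TC, ET) and columns
#'   accuracy, dice, sensitivity, specificity (per-case means).
#' @slot perCase data.frame of per-case, per-region metric values.
#' @export
setClass("MetricsReport",
  representation(summary = "data.frame", perCase = "data.frame"))

#' Hybrid model architecture description
#'
#' Describes the U-Net-style encoder-decoder and, optionally, how a
#' handcrafted [FeatureStack] is fused into it.
#'
#' @slot inputSize spatial input size in pixels (default 256); must be
#'   divisible by 2^length(encoderChannels).
#' @slot inChannels number of imaging channels (default 4 modalities).
#' @slot encoderChannels ordered channel widths of the encoder stages
#'   (default 64, 128, 256, 512).
#' @slot nClasses number of output classes (default 4: background + 3 tumor
#'   sub-regions).
#' @slot fusion one of "none", "input_channel", "feature_map",
#'   "decision_level".
#' @slot handcraftedChannels number of handcrafted feature channels fused in
#'   (ignored when fusion = "none").
#' @slot fusionDepth encoder stage index receiving the feature stack
#'   (feature_map mode only).
#' @export
setClass("HybridModelConfig",
  representation(inputSize = "integer", inChannels = "integer",
                 encoderChannels = "integer", nClasses = "integer",
                 fusion = "character", handcraftedChannels = "integer",
                 fusionDepth = "integer"))

setValidity("HybridModelConfig", function(object) {
  if (object@nClasses < 2L) return("nClasses must be >= 2")
  if (object@handcraftedChannels < 0L) return("handcraftedChannels must be >= 0")
  if (!object@fusion %in% c("none", "input_channel", "feature_map", "decision_level"))
    return("unknown fusion strategy")
  ns <- length(object@encoderChannels)
  if (ns < 1L) return("need at least one encoder stage")
  if (object@inputSize %% (2L^ns) != 0L)
    return("invalid input size: must be divisible by 2^(number of stages)")
  if (object@fusion == "feature_map" &&
      (object@fusionDepth < 1L || object@fusionDepth > ns))
    return("bad fusion point")
  TRUE
})

#' Fitted (or freshly initialized) hybrid segmentation model
#'
#' Holds the layer weights of the encoder-decoder as a flat named list plus
#' bookkeeping describing which input channels of which convolutions consume
#' handcrafted features (used by [zeroFusionWeights()]).
#'
#' @slot config the [HybridModelConfig] the model was built from.
#' @slot params named list of weight arrays and bias vectors.
#' @slot meta internal bookkeeping (layer table, fusion channel map).
#' @export
setClass("HybridModel",
  representation(config = "HybridModelConfig", params = "list", meta = "list"))

#' Per-pixel class prediction
#'
#' @slot probabilities array (height, width, nClasses); nonnegative,
#'   per-pixel sum 1 within 1e-5.
#' @slot labels integer matrix of per-pixel argmax labels in
#'   {0..nClasses-1}, ties broken toward the smaller class index.
#' @export
setClass("PredictionMap",
  representation(probabilities = "array", labels = "matrix"))

setValidity("PredictionMap", function(object) {
  d <- dim(object@probabilities)
  if (length(d) != 3L) return("probabilities must be (height, width, nClasses)")
  if (any(object@probabilities < -1e-8)) return("probabilities must be nonnegative")
  s <- apply(object@probabilities, c(1, 2), sum)
  if (max(abs(s - 1)) > 1e-5) return("per-pixel probabilities must sum to 1")
  TRUE
})

#' Phantom slice generator settings
#'
#' Describes the synthetic multi-modal phantom: a smooth-textured elliptical
#' brain with a deformed-disc tumor carrying three nested sub-regions
#' (enhancing rim inside core inside edema), per-modality contrast offsets and
#' additive Gaussian noise.
#'
#' @slot imageSize image side in pixels (default 64 for tests).
#' @slot tumorRadiusRange min/max tumor (whole-tumor) radius in pixels.
#' @slot ringThickness enhancing-rim thickness in pixels.
#' @slot modalityContrasts 4 x 3 matrix of additive offsets, rows
#'   (T1, T1c, T2, FLAIR), columns (edema, core, enhancing).
#' @slot noiseSd additive Gaussian noise standard deviation (intensity units).
#' @slot backgroundTextureScale smoothing length of the background texture
#'   field, pixels.
#' @slot seed base seed for reproducibility.
#' @export
setClass("PhantomSpec",
  representation(imageSize = "integer", tumorRadiusRange = "numeric",
                 ringThickness = "numeric", modalityContrasts = "matrix",
                 noiseSd = "numeric", backgroundTextureScale = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (object@noiseSd < 0) return("invalid phantom spec: noise_sd must be >= 0")
  rr <- object@tumorRadiusRange
  if (length(rr) != 2L || rr[1] > rr[2] || rr[1] <= 0)
    return("invalid phantom spec: bad tumor radius range")
  # tumor plus deformed edema annulus must fit inside the image
  if (rr[2] * 1.65 + 2 >= object@imageSize / 2)
    return("invalid phantom spec: tumor_radius_range does not fit inside image")
  if (!all(dim(object@modalityContrasts) == c(4L, 3L)))
    return("invalid phantom spec: modalityContrasts must be 4 x 3")
  TRUE
})

#' Training-time augmentation settings
#'
#' Defaults follow the stated augmentation recipe: rotation within +/-15
#' degrees, scaling in [0.8, 1.2], horizontal flip with probability 0.5,
#' elastic deformation smoothed with a Gaussian of sigma 4, intensity shift
#' in [-0.1, 0.1], and contrast normalization by histogram equalization.
#'
#' @slot rotationDeg maximal absolute rotation, degrees.
#' @slot scaleRange multiplicative scale range.
#' @slot hflipProb horizontal flip probability.
#' @slot elasticSigma Gaussian smoothing sigma of the displacement field, px.
#' @slot elasticAlpha displacement amplitude, px (0 disables).
#' @slot intensityShiftRange additive intensity shift range.
#' @slot contrastNorm apply per-channel histogram equalization (with
#'   probability 0.5 when enabled).
#' @slot seed base seed.
#' @export
setClass("AugmentationConfig",
  representation(rotationDeg = "numeric", scaleRange = "numeric",
                 hflipProb = "numeric", elasticSigma = "numeric",
                 elasticAlpha = "numeric", intensityShiftRange = "numeric",
                 contrastNorm = "logical", seed = "integer"))

setValidity("AugmentationConfig", function(object) {
  if (object@hflipProb < 0 || object@hflipProb > 1)
    return("invalid augmentation config: flip probability outside [0,1]")
  if (length(object@scaleRange) != 2L || diff(object@scaleRange) < 0)
    return("invalid augmentation config: scale range not ordered")
  if (length(object@intensityShiftRange) != 2L ||
      diff(object@intensityShiftRange) < 0)
    return("invalid augmentation config: shift range not ordered")
  if (object@elasticSigma <= 0) return("invalid filter scale")
  if (object@elasticAlpha < 0) return("invalid augmentation config: negative alpha")
  TRUE
})

#' SGD training settings
#'
#' Defaults follow the published recipe: momentum 0.9, learning rate 0.0010,
#' weight decay 0.0005, batch size 16, at most 100 epochs, with early
#' stopping on validation loss.
#'
#' @slot momentum,learningRate,weightDecay SGD hyperparameters.
#' @slot batchSize minibatch size.
#' @slot epochs maximal number of epochs.
#' @slot patience early-stopping patience in epochs.
#' @slot seed base seed for shuffling and augmentation draws.
#' @export
setClass("TrainConfig",
  representation(momentum = "numeric", learningRate = "numeric",
                 weightDecay = "numeric", batchSize = "integer",
                 epochs = "integer", patience = "integer", seed = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@momentum < 0 || object@learningRate <= 0 ||
      object@weightDecay < 0 || object@batchSize < 1L || object@epochs < 0L)
    return("training hyperparameters must be positive")
  if (object@patience < 1L) return("patience must be >= 1")
  TRUE
})

#' Training history
#'
#' @slot epoch integer vector of completed epochs.
#' @slot trainLoss,valLoss,valDice per-epoch traces.
#' @slot stoppedAt epoch at which training stopped.
#' @slot bestEpoch epoch whose weights were restored.
#' @slot config list echo of the training configuration used.
#' @export
setClass("TrainHistory",
  representation(epoch = "integer", trainLoss = "numeric",
                 valLoss = "numeric", valDice = "numeric",
                 stoppedAt = "integer", bestEpoch = "integer",
                 config = "list"))
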