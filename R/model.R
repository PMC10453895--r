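#' @include AllClasses.R nn_ops.R utils.R
NULL

#' Construct a HybridModelConfig
#'
#' @param inputSize spatial input size, pixels; must be divisible by
#'   2^(number of encoder stages).
#' @param inChannels imaging channels (4 modalities).
#' @param encoderChannels encoder stage widths.
#' @param nClasses output classes.
#' @param fusion fusion strategy: "none", "input_channel", "feature_map" or
#'   "decision_level".
#' @param handcraftedChannels handcrafted channel count fused in.
#' @param fusionDepth encoder stage receiving the stack (feature_map mode).
#' @return a [HybridModelConfig-class].
#' @export
hybridModelConfig <- function(inputSize = 256L, inChannels = 4L,
                              encoderChannels = c(64L, 128L, 256L, 512L),
                              nClasses = 4L, fusion = "none",
                              handcraftedChannels = 0L, fusionDepth = 1L) {
  cfg <- new("HybridModelConfig", inputSize = as.integer(inputSize),
             inChannels = as.integer(inChannels),
             encoderChannels = as.integer(encoderChannels),
             nClasses = as.integer(nClasses), fusion = fusion,
             handcraftedChannels = as.integer(handcraftedChannels),
             fusionDepth = as.integer(fusionDepth))
  validObject(cfg)
  cfg
}

# decoder output widths: mirror of the encoder, ending at encoderChannels[1]
.decoderWidths <- function(E) {
  ns <- length(E)
  vapply(seq_len(ns), function(i) E[max(i - 1L, 1L)], integer(1))
}

# per-convolution input-channel layout: "b" = computed/base channel,
# "h" = directly injected handcrafted channel
.modelLayout <- function(config) {
  E <- config@encoderChannels
  ns <- length(E)
  k <- if (config@fusion == "none") 0L else config@handcraftedChannels
  fd <- config@fusionDepth
  D <- .decoderWidths(E)
  skipTags <- lapply(seq_len(ns), function(i) {
    tags <- rep("b", E[i])
    if (config@fusion == "feature_map" && i == fd) tags <- c(tags, rep("h", k))
    tags
  })
  layers <- list()
  inTags <- c(rep("b", config@inChannels),
              if (config@fusion == "input_channel") rep("h", k))
  for (i in seq_len(ns)) {
    layers[[paste0("enc", i)]] <- list(kh = 3L, inTags = inTags, cout = E[i])
    inTags <- skipTags[[i]]
  }
  curTags <- skipTags[[ns]]              # pooled bottom feeds the decoder
  for (i in rev(seq_len(ns))) {
    layers[[paste0("dec", i)]] <-
      list(kh = 3L, inTags = c(curTags, skipTags[[i]]), cout = D[i],
           upChannels = length(curTags))
    curTags <- rep("b", D[i])
  }
  outTags <- c(rep("b", D[1]),
               if (config@fusion == "decision_level") rep("h", k))
  layers[["out"]] <- list(kh = 1L, inTags = outTags, cout = config@nClasses)
  list(layers = layers, skipTags = skipTags, decoderWidths = D, k = k)
}

# seeded He-style initialization; base-channel weights are drawn first with a
# per-layer seed so that a hybrid model shares its non-fusion weights
# bit-exactly with the baseline built from the same seed
.initParams <- function(layout, seed) {
  params <- list()
  fusionSlices <- list()
  li <- 0L
  for (nm in names(layout$layers)) {
    li <- li + 1L
    ly <- layout$layers[[nm]]
    cin <- length(ly$inTags)
    baseIdx <- which(ly$inTags == "b")
    extraIdx <- which(ly$inTags == "h")
    sd <- sqrt(2 / (ly$kh^2 * length(baseIdx)))
    W <- array(0, dim = c(ly$kh, ly$kh, cin, ly$cout))
    W[, , baseIdx, ] <- .withSeed(.deriveSeed(seed, li),
      rnorm(ly$kh^2 * length(baseIdx) * ly$cout, sd = sd))
    if (length(extraIdx)) {
      W[, , extraIdx, ] <- .withSeed(.deriveSeed(seed, 1000L + li),
        rnorm(ly$kh^2 * length(extraIdx) * ly$cout, sd = sd))
      fusionSlices[[nm]] <- extraIdx
    }
    params[[paste0(nm, "_W")]] <- W
    params[[paste0(nm, "_b")]] <- numeric(ly$cout)
  }
  list(params = params, fusionSlices = fusionSlices)
}

.layerTable <- function(config, layout) {
  ns <- length(config@encoderChannels)
  sz <- config@inputSize
  rows <- list(data.frame(layer = "input", outputSize = sz,
                          channels = length(layout$layers$enc1$inTags)))
  res <- sz
  for (i in seq_len(ns)) {
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("enc%d (conv 3x3 + ReLU)", i), outputSize = res,
      channels = config@encoderChannels[i])
    res <- res %/% 2L
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("pool%d (max 2x2)", i), outputSize = res,
      channels = length(layout$skipTags[[i]]))
  }
  for (i in rev(seq_len(ns))) {
    res <- res * 2L
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("dec%d (up 2x + conv 3x3 + ReLU)", i),
      outputSize = res, channels = layout$decoderWidths[i])
  }
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "out (conv 1x1 + softmax)", outputSize = sz,
    channels = config@nClasses)
  do.call(rbind, rows)
}

#' Build the baseline encoder-decoder CNN
#'
#' A symmetric U-Net-style network: each encoder stage is a 3x3 convolution
#' + ReLU followed by 2x2 max pooling (halving the resolution), with channel
#' widths `encoderChannels`; the mirrored decoder doubles the resolution per
#' stage by nearest-neighbor upsampling, concatenates the skip connection
#' from the matching encoder stage and applies a 3x3 convolution + ReLU; a
#' final 1x1 convolution maps to `nClasses` with a per-pixel softmax, so a
#' 256 x 256 x 4 input yields a 256 x 256 x 4 class-probability output.
#'
#' @param config a [hybridModelConfig()] with `fusion = "none"`.
#' @param seed seed for the weight initialization.
#' @return a [HybridModel-class].
#' @export
buildCNN <- function(config = hybridModelConfig(), seed = 1L) {
  validObject(config)
  if (config@fusion != "none")
    stop("buildCNN requires fusion = \"none\"; use buildHybrid")
  layout <- .modelLayout(config)
  ini <- .initParams(layout, seed)
  new("HybridModel", config = config, params = ini$params,
      meta = list(layout = layout, fusionSlices = ini$fusionSlices,
                  layerTable = .layerTable(config, layout), seed = seed))
}

#' Build a hybrid model fusing handcrafted features into the CNN
#'
#' Identical to [buildCNN()] except for the fusion pathway:
#' * `input_channel`: the feature stack is concatenated to the modality
#'   channels, so the first convolution consumes `inChannels + k` channels;
#' * `feature_map`: the stack is downsampled by average pooling to the
#'   resolution of encoder stage `fusionDepth` and concatenated to that
#'   stage's feature map (both the skip connection and the pooled pathway
#'   see it);
#' * `decision_level`: the stack is concatenated to the last decoder feature
#'   map, so the final 1x1 classifier consumes `decoderWidth + k` channels.
#'
#' Weights of non-fusion channels are shared bit-exactly with the baseline
#' built from the same seed, so zeroing the fusion slices
#' ([zeroFusionWeights()]) reproduces the baseline network.
#'
#' @param config a [hybridModelConfig()] with `fusion != "none"`.
#' @param k handcrafted channel count (defaults to the config's).
#' @param seed seed for the weight initialization.
#' @return a [HybridModel-class].
#' @export
buildHybrid <- function(config, k = config@handcraftedChannels, seed = 1L) {
  if (config@fusion == "none") stop("buildHybrid requires fusion != \"none\"")
  if (k < 1L) stop("no handcrafted channels")
  config@handcraftedChannels <- as.integer(k)
  validObject(config)
  layout <- .modelLayout(config)
  ini <- .initParams(layout, seed)
  new("HybridModel", config = config, params = ini$params,
      meta = list(layout = layout, fusionSlices = ini$fusionSlices,
                  layerTable = .layerTable(config, layout), seed = seed))
}

#' Zero the weights consuming handcrafted feature channels
#'
#' After zeroing, the hybrid model computes exactly the baseline CNN built
#' from the same seed, whatever the feature stack contains.
#'
#' @param model a [HybridModel-class].
#' @return the model with fusion weight slices set to 0.
#' @export
zeroFusionWeights <- function(model) {
  for (nm in names(model@meta$fusionSlices)) {
    idx <- model@meta$fusionSlices[[nm]]
    model@params[[paste0(nm, "_W")]][, , idx, ] <- 0
  }
  model
}

#' Model summary
#'
#' @param model a [HybridModel-class].
#' @param path optional path; when given, the summary is written as JSON.
#' @return data.frame with layer name, output size and channels.
#' @export
modelSummary <- function(model, path = NULL) {
  tb <- model@meta$layerTable
  if (!is.null(path))
    writeLines(jsonlite::toJSON(tb, dataframe = "rows", auto_unbox = TRUE),
               path)
  tb
}

#' Save / load model weights
#'
#' Checkpoints use R's native serialization and carry the config, weights
#' and bookkeeping needed to resume.
#'
#' @param model a [HybridModel-class].
#' @param path checkpoint file path.
#' @return `path` invisibly for `saveModel`; the model for `loadModel`.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(config = model@config, params = model@params,
               meta = model@meta), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  new("HybridModel", config = x$config, params = x$params, meta = x$meta)
}

## --- forward / backward ------------------------------------------------

# X: (H, W, N, inChannels); FS: (H, W, N, k) or NULL
.forwardModel <- function(model, X, FS = NULL, wantCache = FALSE) {
  cfg <- model@config
  E <- cfg@encoderChannels
  ns <- length(E)
  fuse <- cfg@fusion
  if (fuse != "none" && is.null(FS)) stop("fusion input required")
  p <- model@params
  cache <- list(encIn = vector("list", ns), encZ = vector("list", ns),
                poolMasks = vector("list", ns), skipDim = vector("list", ns),
                decIn = vector("list", ns), decZ = vector("list", ns))
  cur <- if (fuse == "input_channel") .concatC(X, FS) else X
  skips <- vector("list", ns)
  for (i in seq_len(ns)) {
    cache$encIn[[i]] <- cur
    Z <- .convForward(cur, p[[paste0("enc", i, "_W")]],
                      p[[paste0("enc", i, "_b")]])
    cache$encZ[[i]] <- Z
    A <- .reluForward(Z)
    if (fuse == "feature_map" && i == cfg@fusionDepth)
      A <- .concatC(A, .avgPoolTimes(FS, i - 1L))
    skips[[i]] <- A
    cache$skipDim[[i]] <- dim(A)
    mp <- .maxPoolForward(A)
    cache$poolMasks[[i]] <- mp$masks
    cur <- mp$Y
  }
  for (i in rev(seq_len(ns))) {
    up <- .upsampleForward(cur)
    cin <- .concatC(up, skips[[i]])
    cache$decIn[[i]] <- cin
    Z <- .convForward(cin, p[[paste0("dec", i, "_W")]],
                      p[[paste0("dec", i, "_b")]])
    cache$decZ[[i]] <- Z
    cur <- .reluForward(Z)
  }
  outIn <- if (fuse == "decision_level") .concatC(cur, FS) else cur
  cache$outIn <- outIn
  logits <- .convForward(outIn, p$out_W, p$out_b)
  probs <- .softmaxC(logits)
  if (wantCache) list(probs = probs, cache = cache) else list(probs = probs)
}

.backwardModel <- function(model, cache, dLogits) {
  cfg <- model@config
  E <- cfg@encoderChannels
  ns <- length(E)
  D <- model@meta$layout$decoderWidths
  p <- model@params
  grads <- list()
  ob <- .convBackward(cache$outIn, p$out_W, dLogits)
  grads$out_W <- ob$dW; grads$out_b <- ob$db
  dCur <- if (cfg@fusion == "decision_level")
    ob$dX[, , , seq_len(D[1]), drop = FALSE] else ob$dX
  dSkipDec <- vector("list", ns)
  dBottom <- NULL
  for (i in seq_len(ns)) {          # decoder stages, shallow to deep
    dZ <- .reluBackward(cache$decZ[[i]], dCur)
    cb <- .convBackward(cache$decIn[[i]], p[[paste0("dec", i, "_W")]], dZ)
    grads[[paste0("dec", i, "_W")]] <- cb$dW
    grads[[paste0("dec", i, "_b")]] <- cb$db
    cup <- model@meta$layout$layers[[paste0("dec", i)]]$upChannels
    nAll <- dim(cb$dX)[4]
    dUp <- cb$dX[, , , seq_len(cup), drop = FALSE]
    dSkipDec[[i]] <- cb$dX[, , , (cup + 1L):nAll, drop = FALSE]
    dDown <- .upsampleBackward(dUp)
    if (i < ns) dCur <- dDown else dBottom <- dDown
  }
  dPool <- dBottom                  # gradient w.r.t. the pooled bottom
  for (i in rev(seq_len(ns))) {
    dA <- .maxPoolBackward(dPool, cache$poolMasks[[i]], cache$skipDim[[i]]) +
      dSkipDec[[i]]
    dZ <- .reluBackward(cache$encZ[[i]], dA[, , , seq_len(E[i]), drop = FALSE])
    cb <- .convBackward(cache$encIn[[i]], p[[paste0("enc", i, "_W")]], dZ)
    grads[[paste0("enc", i, "_W")]] <- cb$dW
    grads[[paste0("enc", i, "_b")]] <- cb$db
    if (i > 1L) dPool <- cb$dX
  }
  grads
}

# combined CE + soft-Dice loss and its gradient w.r.t. the logits, over a
# batch; labels: (H, W, N) integer array in 0..nClasses-1
.lossAndGrad <- function(probs, labels, epsilon = 1e-6) {
  d <- dim(probs)
  npix <- d[1] * d[2] * d[3]
  C <- d[4]
  P <- probs; dim(P) <- c(npix, C)
  y <- as.integer(as.vector(labels))
  Y <- matrix(0, npix, C)
  Y[cbind(seq_len(npix), y + 1L)] <- 1
  pTrue <- P[cbind(seq_len(npix), y + 1L)]
  ce <- mean(-log(pmin(pmax(pTrue, 1e-7), 1)))
  G <- matrix(0, npix, C)           # dLoss/dP
  ratios <- numeric(C - 1L)
  for (cl in seq_len(C - 1L)) {
    yc <- Y[, cl + 1L]; pc <- P[, cl + 1L]
    sy <- sum(yc); sp <- sum(pc); syp <- sum(yc * pc)
    den <- sy + sp + epsilon
    ratios[cl] <- (2 * syp + epsilon) / den
    G[, cl + 1L] <- -(2 * yc * den - (2 * syp + epsilon)) / den^2 / (C - 1L)
  }
  diceTerm <- 1 - mean(ratios)
  ## chain the dice gradient through the softmax; add the CE softmax grad
  dLogits <- P * (G - rowSums(G * P)) + (P - Y) / npix
  dim(dLogits) <- d
  list(ce = ce, diceTerm = diceTerm, total = ce + diceTerm,
       dLogits = dLogits)
}

## --- prediction --------------------------------------------------------

# stack a list of MultiModalSlice into (H, W, N, C)
.sliceBatch <- function(slices) {
  p1 <- pixelData(slices[[1]])
  d <- dim(p1)
  X <- array(0, dim = c(d[2], d[3], length(slices), d[1]))
  for (n in seq_along(slices)) {
    pn <- pixelData(slices[[n]])
    for (cc in seq_len(d[1])) X[, , n, cc] <- pn[cc, , ]
  }
  X
}

.stackBatch <- function(stacks) {
  c1 <- stackChannels(stacks[[1]])
  d <- dim(c1)
  X <- array(0, dim = c(d[2], d[3], length(stacks), d[1]))
  for (n in seq_along(stacks)) {
    cn <- stackChannels(stacks[[n]])
    for (cc in seq_len(d[1])) X[, , n, cc] <- cn[cc, , ]
  }
  X
}

#' Predict class probabilities and labels for slices
#'
#' Runs the model in evaluation mode (deterministic for fixed weights) on
#' one slice or a batch. Per-pixel probabilities are softmax-normalized;
#' labels are the per-pixel argmax, ties broken toward the smaller class
#' index.
#'
#' @param model a [HybridModel-class].
#' @param slices a [MultiModalSlice-class] or list of them.
#' @param featureStacks matching [FeatureStack-class] (list), required
#'   iff the model's fusion is not "none".
#' @return a [PredictionMap-class], or a list of them for a list input.
#' @export
forwardPredict <- function(model, slices, featureStacks = NULL) {
  single <- is(slices, "MultiModalSlice")
  if (single) {
    slices <- list(slices)
    if (!is.null(featureStacks) && is(featureStacks, "FeatureStack"))
      featureStacks <- list(featureStacks)
  }
  X <- .sliceBatch(slices)
  FS <- NULL
  if (model@config@fusion != "none") {
    if (is.null(featureStacks)) stop("fusion input required")
    FS <- .stackBatch(featureStacks)
  }
  probs <- .forwardModel(model, X, FS)$probs
  d <- dim(probs)
  out <- lapply(seq_len(d[3]), function(n) {
    pn <- array(probs[, , n, ], dim = c(d[1], d[2], d[4]))
    M <- matrix(pn, d[1] * d[2], d[4])
    lab <- matrix(max.col(M, ties.method = "first") - 1L, d[1], d[2])
    new("PredictionMap", probabilities = pn, labels = lab)
  })
  if (single) out[[1]] else out
}
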