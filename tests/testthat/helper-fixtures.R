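# shared fixtures: tiny phantom volumes/slices built in code

# a small multi-modal volume with an off-center bright blob and matching
# nested labels on a subset of slices
makeTestVolume <- function(nSlices = 6L, side = 24L, seed = 1L) {
  set.seed(seed)
  vox <- array(0, dim = c(4L, nSlices, side, side))
  lab <- array(0L, dim = c(nSlices, side, side))
  ctr <- side / 2
  xg <- matrix(rep(seq_len(side), each = side), side, side)
  yg <- matrix(rep(seq_len(side), times = side), side, side)
  brain <- (xg - ctr)^2 + (yg - ctr)^2 <= (0.45 * side)^2
  for (s in seq_len(nSlices)) {
    hasTumor <- s %% 2L == 0L
    for (m in 1:4) {
      ch <- matrix(0, side, side)
      ch[brain] <- 100 + 10 * m + rnorm(sum(brain), sd = 5)
      vox[m, s, , ] <- ch
    }
    if (hasTumor) {
      r2 <- (xg - ctr - 3)^2 + (yg - ctr)^2
      sl <- matrix(0L, side, side)
      sl[r2 <= 16] <- 1L
      sl[r2 <= 9] <- 3L
      sl[r2 <= 4] <- 2L
      sl[!brain] <- 0L
      lab[s, , ] <- sl
      vox[4, s, , ][sl > 0] <- vox[4, s, , ][sl > 0] + 40
    }
  }
  list(volume = MultiModalVolume(vox), mask = SegmentationMask(lab))
}

makeTestSlicePair <- function(side = 32L, seed = 5L) {
  sp <- phantomSpec(imageSize = side,
                    tumorRadiusRange = c(side / 8, side * 0.22), seed = seed)
  generatePhantomSlice(sp, seed = seed)
}

tinyModelConfig <- function(fusion = "none", k = 0L, fusionDepth = 1L) {
  hybridModelConfig(inputSize = 16L, inChannels = 4L,
                    encoderChannels = c(3L, 5L), nClasses = 4L,
                    fusion = fusion, handcraftedChannels = as.integer(k),
                    fusionDepth = as.integer(fusionDepth))
}

randomBatch <- function(h = 16L, n = 1L, c = 4L, seed = 1L) {
  set.seed(seed)
  list(X = array(runif(h * h * n * c), dim = c(h, h, n, c)),
       labs = array(sample(0:3, h * h * n, replace = TRUE), dim = c(h, h, n)))
}
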