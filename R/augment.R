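#' @include AllClasses.R utils.R io_preprocess.R
NULL

#' Construct an AugmentationConfig
#'
#' Defaults follow the stated recipe: rotation within +/-15 degrees, scaling
#' by a factor in \[0.8, 1.2\], horizontal flip with probability 0.5,
#' elastic deformation smoothed with a Gaussian of sigma 4 (amplitude 10
#' px), intensity shift in \[-0.1, 0.1\] and contrast normalization by
#' histogram equalization (applied with probability 0.5 when enabled).
#'
#' @param rotationDeg,scaleRange,hflipProb,elasticSigma,elasticAlpha,intensityShiftRange,contrastNorm,seed
#'   see [AugmentationConfig-class].
#' @return an [AugmentationConfig-class].
#' @export
augmentationConfig <- function(rotationDeg = 15, scaleRange = c(0.8, 1.2),
                               hflipProb = 0.5, elasticSigma = 4.0,
                               elasticAlpha = 10, intensityShiftRange = c(-0.1, 0.1),
                               contrastNorm = TRUE, seed = 1L) {
  cfg <- new("AugmentationConfig", rotationDeg = rotationDeg,
             scaleRange = as.numeric(scaleRange), hflipProb = hflipProb,
             elasticSigma = elasticSigma, elasticAlpha = elasticAlpha,
             intensityShiftRange = as.numeric(intensityShiftRange),
             contrastNorm = contrastNorm, seed = as.integer(seed))
  validObject(cfg)
  cfg
}

# identity-config shortcut used to keep disabled augmentation bit-exact
.isIdentityGeom <- function(theta, scale, flip) {
  theta == 0 && scale == 1 && !flip
}

# joint backward affine warp about the image center: bilinear for intensity
# channels, nearest for labels; exposed borders are zero-padded
.warpPair <- function(pix, labels, theta, scale, flip) {
  h <- dim(pix)[2]; w <- dim(pix)[3]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  xg <- rep(seq_len(w), each = h) - cx
  yg <- rep(seq_len(h), times = w) - cy
  th <- -theta          # backward map uses the inverse rotation
  xs <- (cos(th) * xg - sin(th) * yg) / scale
  ys <- (sin(th) * xg + cos(th) * yg) / scale
  if (flip) xs <- -xs
  xs <- xs + cx; ys <- ys + cy
  out <- pix
  for (m in seq_len(dim(pix)[1]))
    out[m, , ] <- matrix(.sampleBilinear(matrix(pix[m, , ], h, w), xs, ys),
                         h, w)
  lab <- matrix(as.integer(.sampleNearest(labels, xs, ys, fill = 0L)), h, w)
  list(pix = out, labels = lab)
}

#' Elastic deformation of a slice/mask pair
#'
#' Draws a random displacement field (white noise Gaussian-filtered with
#' `sigma`, rescaled so the largest displacement magnitude equals `alpha`
#' pixels) and applies it by backward warping, bilinear for the intensity
#' channels and nearest-neighbor for the labels. The same field deforms
#' image and mask; `alpha = 0` is the exact identity.
#'
#' @param slice a [MultiModalSlice-class].
#' @param mask the congruent [SegmentationMask-class].
#' @param sigma Gaussian filter scale, pixels (> 0).
#' @param alpha displacement amplitude, pixels (>= 0).
#' @param seed draw seed.
#' @return `list(slice=, mask=)`.
#' @export
elasticDeformation <- function(slice, mask, sigma = 4.0, alpha = 10,
                               seed = 1L) {
  if (sigma <= 0) stop("invalid filter scale")
  if (alpha < 0) stop("alpha must be >= 0")
  pix <- pixelData(slice)
  labels <- maskLabels(mask)
  if (!all(dim(labels) == dim(pix)[2:3])) stop("unaligned masks")
  if (alpha == 0)
    return(list(slice = slice, mask = mask))
  h <- dim(pix)[2]; w <- dim(pix)[3]
  fld <- .withSeed(seed, {
    dx <- .gaussianBlur(matrix(rnorm(h * w), h, w), sigma)
    dy <- .gaussianBlur(matrix(rnorm(h * w), h, w), sigma)
    list(dx = dx, dy = dy)
  })
  mx <- max(sqrt(fld$dx^2 + fld$dy^2))
  sc <- if (mx > 0) alpha / mx else 0
  dx <- fld$dx * sc; dy <- fld$dy * sc
  xs <- rep(seq_len(w), each = h) + as.vector(dx)
  ys <- rep(seq_len(h), times = w) + as.vector(dy)
  out <- pix
  for (m in seq_len(dim(pix)[1]))
    out[m, , ] <- matrix(.sampleBilinear(matrix(pix[m, , ], h, w), xs, ys),
                         h, w)
  lab <- matrix(as.integer(.sampleNearest(labels, xs, ys, fill = 0L)), h, w)
  list(slice = MultiModalSlice(out, sourceIndex = slice@sourceIndex),
       mask = SegmentationMask(lab))
}

#' Stochastic augmentation of a slice/mask pair
#'
#' Draws one rotation in \[-rotationDeg, +rotationDeg\], one scale factor in
#' `scaleRange`, a horizontal flip with probability `hflipProb`, an elastic
#' deformation (when `elasticAlpha > 0`), an additive intensity shift in
#' `intensityShiftRange` applied to all channels then clipped to \[0, 1\],
#' and (when `contrastNorm`) per-channel histogram equalization with
#' probability 0.5. The identical geometric transform is applied to the
#' image (bilinear) and the mask (nearest-neighbor), so no interpolated
#' labels can appear. The fixed stage order is geometric, then elastic, then
#' intensity shift, then contrast. Deterministic given `seed`; with every
#' stochastic component disabled the pair is returned bit-exactly.
#'
#' @param slice a [MultiModalSlice-class].
#' @param mask the congruent [SegmentationMask-class].
#' @param config an [augmentationConfig()].
#' @param seed draw seed for this pair.
#' @return `list(slice=, mask=)`.
#' @export
augmentPair <- function(slice, mask, config = augmentationConfig(),
                        seed = config@seed) {
  validObject(config)
  pix <- pixelData(slice)
  labels <- maskLabels(mask)
  if (!all(dim(labels) == dim(pix)[2:3])) stop("unaligned masks")
  draws <- .withSeed(seed, {
    list(theta = runif(1, -config@rotationDeg, config@rotationDeg) * pi / 180,
         scale = runif(1, config@scaleRange[1], config@scaleRange[2]),
         flip = runif(1) < config@hflipProb,
         elasticSeed = .deriveSeed(seed, 4L),
         shift = runif(1, config@intensityShiftRange[1],
                       config@intensityShiftRange[2]),
         equalize = runif(1) < 0.5)
  })
  if (!.isIdentityGeom(draws$theta, draws$scale, draws$flip)) {
    wp <- .warpPair(pix, labels, draws$theta, draws$scale, draws$flip)
    pix <- wp$pix; labels <- wp$labels
  }
  if (config@elasticAlpha > 0) {
    el <- elasticDeformation(MultiModalSlice(pix, slice@sourceIndex),
                             SegmentationMask(labels),
                             sigma = config@elasticSigma,
                             alpha = config@elasticAlpha,
                             seed = draws$elasticSeed)
    pix <- pixelData(el$slice); labels <- maskLabels(el$mask)
  }
  if (draws$shift != 0) pix <- pmin(pmax(pix + draws$shift, 0), 1)
  if (config@contrastNorm && draws$equalize) {
    for (m in seq_len(dim(pix)[1]))
      pix[m, , ] <- matrix(.histEqualize(pix[m, , ]),
                           dim(pix)[2], dim(pix)[3])
  }
  list(slice = MultiModalSlice(pix, sourceIndex = slice@sourceIndex),
       mask = SegmentationMask(labels))
}
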