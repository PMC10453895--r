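#' @include AllClasses.R features_dsurf.R features_hog.R features_texture.R
NULL

# nearest-keypoint upsampling of a per-grid-point value matrix to full
# resolution: each pixel (0-based) takes the value of its nearest grid
# coordinate (exact midpoints go to the upper neighbor)
.gridUpsample <- function(vals, coords, extent) {
  p0 <- seq_len(extent) - 1L
  idx <- if (length(coords) == 1L) rep(1L, extent)
         else findInterval(p0, coords[-length(coords)] + diff(coords) / 2) + 1L
  vals[idx, , drop = FALSE]
}

#' Assemble an image-aligned feature stack
#'
#' Combines handcrafted descriptor outputs into one channel stack aligned to
#' the image grid, ready for fusion into the network:
#' * `dsurf` output ([dsurfDescriptors()]): the 64 descriptor dimensions are
#'   scattered to their grid positions and nearest-neighbor upsampled to full
#'   resolution, so each channel is piecewise constant on step-sized cells
#'   (optionally restricted to `dsurfChannels`);
#' * `hog` output ([hogFeatures()]): the per-pixel cell-histogram maps are
#'   appended;
#' * `texture` output ([textureIntensityMaps()]): its channels are appended.
#'
#' @param imageShape integer pair c(height, width).
#' @param dsurf optional [dsurfDescriptors()] result.
#' @param hog optional [hogFeatures()] result.
#' @param texture optional [FeatureStack-class] from
#'   [textureIntensityMaps()].
#' @param dsurfChannels optional integer subset of the 64 descriptor
#'   dimensions to keep.
#' @return a [FeatureStack-class]; the provenance records each channel
#'   group's descriptor and parameters.
#' @export
featureStack <- function(imageShape, dsurf = NULL, hog = NULL, texture = NULL,
                         dsurfChannels = NULL) {
  h <- imageShape[1]; w <- imageShape[2]
  if (is.null(dsurf) && is.null(hog) && is.null(texture))
    stop("unaligned features: no descriptor outputs supplied")
  chans <- list()
  prov <- list()
  if (!is.null(dsurf)) {
    kp <- dsurf$keypoints
    if (nrow(kp) == 0L) stop("unaligned features: empty DSURF grid")
    xs <- sort(unique(kp$x)); ys <- sort(unique(kp$y))
    if (nrow(kp) != length(xs) * length(ys))
      stop("unaligned features: DSURF keypoints do not form a full grid")
    keep <- if (is.null(dsurfChannels)) seq_len(64L) else as.integer(dsurfChannels)
    step <- dsurf$step
    for (ch in keep) {
      # descriptors are ordered row-major (x fastest), matching denseGrid
      grid <- matrix(dsurf$descriptors[, ch], nrow = length(ys),
                     ncol = length(xs), byrow = TRUE)
      up <- .gridUpsample(grid, ys, h)
      up <- t(.gridUpsample(t(up), xs, w))
      chans[[length(chans) + 1L]] <- up
    }
    prov$dsurf <- list(descriptor = "dense SURF", step = step,
                       window = dsurf$window, channels = keep)
  }
  if (!is.null(hog)) {
    for (b in seq_len(dim(hog$maps)[1]))
      chans[[length(chans) + 1L]] <- matrix(hog$maps[b, , ], h, w)
    prov$hog <- list(descriptor = "HOG cell histograms",
                     params = unclass(hog$params))
  }
  if (!is.null(texture)) {
    tc <- stackChannels(texture)
    for (b in seq_len(dim(tc)[1]))
      chans[[length(chans) + 1L]] <- matrix(tc[b, , ], h, w)
    prov <- c(prov, texture@provenance)
  }
  shapes <- vapply(chans, function(m) all(dim(m) == c(h, w)), logical(1))
  if (!all(shapes)) stop("unaligned features: channel shape mismatch")
  arr <- array(0, dim = c(length(chans), h, w))
  for (i in seq_along(chans)) arr[i, , ] <- chans[[i]]
  if (!all(is.finite(arr))) stop("unaligned features: non-finite channel values")
  new("FeatureStack", channels = arr, provenance = prov)
}

#' Extract a handcrafted feature stack from one multi-modal slice
#'
#' Convenience wrapper running the selected descriptors on one modality
#' channel (FLAIR by default, where tumor contrast is strongest) and
#' assembling the result with [featureStack()].
#'
#' @param slice a [MultiModalSlice-class].
#' @param features subset of c("hog", "dsurf", "texture").
#' @param channel modality channel index used for extraction (4 = FLAIR).
#' @param dsurfStep,dsurfWindow,dsurfSigma dense SURF settings.
#' @param hogParams a [hogParams()] list.
#' @param textureWindow window for [textureIntensityMaps()].
#' @param dsurfChannels optional descriptor-dimension subset.
#' @return a [FeatureStack-class].
#' @export
extractFeatures <- function(slice, features = c("hog"), channel = 4L,
                            dsurfStep = 8L, dsurfWindow = 16L,
                            dsurfSigma = 1.6, hogParams = hybridSeg::hogParams(),
                            textureWindow = 7L, dsurfChannels = NULL) {
  img <- matrix(pixelData(slice)[channel, , ],
                dim(pixelData(slice))[2], dim(pixelData(slice))[3])
  args <- list(imageShape = dim(img))
  if ("dsurf" %in% features)
    args$dsurf <- dsurfDescriptors(img, step = dsurfStep, sigma = dsurfSigma,
                                   window = dsurfWindow)
  if ("hog" %in% features)
    args$hog <- hogFeatures(img, hogParams)
  if ("texture" %in% features)
    args$texture <- textureIntensityMaps(img, window = textureWindow)
  args$dsurfChannels <- dsurfChannels
  do.call(featureStack, args)
}
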