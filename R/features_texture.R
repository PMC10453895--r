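#' @include utils.R AllClasses.R
NULL

# summed-area-table box sums with windows truncated at the borders
.boxSum <- function(m, half) {
  h <- nrow(m); w <- ncol(m)
  S <- apply(m, 2, cumsum)
  S <- t(apply(S, 1, cumsum))
  S0 <- rbind(0, cbind(0, S))
  r1 <- pmax(seq_len(h) - half, 1L); r2 <- pmin(seq_len(h) + half, h)
  c1 <- pmax(seq_len(w) - half, 1L); c2 <- pmin(seq_len(w) + half, w)
  S0[r2 + 1L, c2 + 1L] - S0[r1, c2 + 1L] - S0[r2 + 1L, c1] + S0[r1, c1]
}

# equal-width quantization of [0,1] intensities to levels 0..L-1
.quantizeLevels <- function(image, levels) {
  x <- pmin(pmax(image, 0), 1)
  pmin(floor(x * levels), levels - 1L)
}

#' Gray-level co-occurrence matrix of an image
#'
#' Counts pairs of quantized intensity levels at the spatial offset
#' `(dRow, dCol)`. In symmetric mode each pair is counted in both orders;
#' with `normalize = TRUE` entries sum to 1. Intensities are quantized by
#' equal-width binning of \[0, 1\] into `levels` levels.
#'
#' @param image numeric matrix with intensities in \[0, 1\].
#' @param levels number of gray levels (>= 2).
#' @param offset integer pair `c(dRow, dCol)`.
#' @param symmetric count both pair orders.
#' @param normalize divide by the total count.
#' @return `levels` x `levels` matrix.
#' @export
glcmMatrix <- function(image, levels = 8L, offset = c(0L, 1L),
                       symmetric = TRUE, normalize = TRUE) {
  if (levels < 2L) stop("invalid quantization: levels must be >= 2")
  q <- .quantizeLevels(image, levels)
  h <- nrow(q); w <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  rs <- seq_len(h); cs <- seq_len(w)
  rs <- rs[rs + dr >= 1L & rs + dr <= h]
  cs <- cs[cs + dc >= 1L & cs + dc <= w]
  G <- matrix(0, levels, levels)
  if (length(rs) && length(cs)) {
    a <- q[rs, cs, drop = FALSE]
    b <- q[rs + dr, cs + dc, drop = FALSE]
    tab <- table(factor(a, levels = 0:(levels - 1L)),
                 factor(b, levels = 0:(levels - 1L)))
    G <- matrix(as.numeric(tab), levels, levels)
    if (symmetric) G <- G + t(G)
  }
  if (normalize && sum(G) > 0) G <- G / sum(G)
  G
}

# per-window GLCM contrast/homogeneity/energy maps for one offset
.glcmWindowMaps <- function(q, levels, offset, half) {
  h <- nrow(q); w <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  valid <- matrix(FALSE, h, w)
  rs <- seq_len(h); cs <- seq_len(w)
  rs <- rs[rs + dr >= 1L & rs + dr <= h]
  cs <- cs[cs + dc >= 1L & cs + dc <= w]
  if (!length(rs) || !length(cs))
    return(list(contrast = matrix(0, h, w), homogeneity = matrix(1, h, w),
                energy = matrix(1, h, w)))
  valid[rs, cs] <- TRUE
  q2 <- matrix(0L, h, w)
  q2[rs, cs] <- q[rs + dr, cs + dc, drop = FALSE]
  diff2 <- (q - q2)^2
  diff2[!valid] <- 0
  nPairs <- .boxSum(valid + 0, half)
  safeN <- pmax(nPairs, 1)
  contrast <- .boxSum(diff2, half) / safeN
  hom <- valid / (1 + (q - q2)^2)
  homogeneity <- .boxSum(hom, half) / safeN
  homogeneity[nPairs == 0] <- 1
  ## energy needs per-level-pair windowed counts of the symmetric GLCM
  energy <- matrix(0, h, w)
  for (a in 0:(levels - 1L)) {
    for (b in a:(levels - 1L)) {
      I <- valid & ((q == a & q2 == b) | (q == b & q2 == a))
      if (!any(I)) next
      np <- .boxSum(I + 0, half)          # unordered pair count per window
      P <- if (a == b) np / safeN else np / (2 * safeN)  # symmetric P(a,b)
      energy <- energy + (if (a == b) P^2 else 2 * P^2)
    }
  }
  energy[nPairs == 0] <- 1
  contrast[nPairs == 0] <- 0
  list(contrast = contrast, homogeneity = homogeneity, energy = energy)
}

#' 8-neighbor local binary pattern codes
#'
#' Each pixel's code sets one bit per neighbor satisfying
#' neighbor >= center, bits ordered clockwise from the top-left neighbor
#' (bit values 1, 2, 4, ..., 128); borders are replicated. A constant image
#' therefore codes to 255 everywhere.
#'
#' @param image numeric matrix.
#' @param radius neighbor radius in pixels.
#' @return integer-valued matrix of codes in 0..255.
#' @export
lbpMap <- function(image, radius = 1L) {
  offs <- matrix(c(-1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1),
                 ncol = 2, byrow = TRUE) * radius
  lbp <- matrix(0, nrow(image), ncol(image))
  for (i in seq_len(8)) {
    nb <- .shiftReplicate(.shiftReplicate(image, offs[i, 1], 1L),
                          offs[i, 2], 2L)
    lbp <- lbp + 2^(i - 1) * (nb >= image)
  }
  lbp
}

#' Sliding-window intensity and texture feature maps
#'
#' Builds image-aligned channels: local mean, median and standard deviation
#' over a `window` x `window` neighborhood (truncated at borders); GLCM
#' contrast, homogeneity and energy computed per window from a symmetric,
#' normalized co-occurrence matrix over `glcmLevels` equal-width levels
#' (averaged over `glcmOffsets`); and the 8-neighbor local-binary-pattern
#' code map (neighbor >= center, bits clockwise from the top-left neighbor,
#' scaled to \[0, 1\] by 255).
#'
#' @param image numeric matrix with intensities in \[0, 1\].
#' @param window odd window side, pixels.
#' @param glcmLevels number of gray levels (>= 2).
#' @param glcmOffsets list of `c(dRow, dCol)` offsets.
#' @param lbpRadius LBP neighbor radius, pixels.
#' @return a [FeatureStack-class] with channels mean, median, sd,
#'   glcm_contrast, glcm_homogeneity, glcm_energy, lbp.
#' @export
textureIntensityMaps <- function(image, window = 7L, glcmLevels = 8L,
                                 glcmOffsets = list(c(0L, 1L), c(1L, 0L)),
                                 lbpRadius = 1L) {
  if (window %% 2L != 1L) stop("window must be odd")
  if (glcmLevels < 2L) stop("invalid quantization: levels must be >= 2")
  h <- nrow(image); w <- ncol(image)
  half <- window %/% 2L
  cnt <- .boxSum(matrix(1, h, w), half)
  mu <- .boxSum(image, half) / cnt
  ex2 <- .boxSum(image^2, half) / cnt
  sdm <- sqrt(pmax(ex2 - mu^2, 0))

  med <- matrix(0, h, w)
  for (r in seq_len(h)) {
    r1 <- max(1L, r - half); r2 <- min(h, r + half)
    for (cc in seq_len(w)) {
      c1 <- max(1L, cc - half); c2 <- min(w, cc + half)
      med[r, cc] <- stats::median(image[r1:r2, c1:c2])
    }
  }

  q <- .quantizeLevels(image, glcmLevels)
  con <- hom <- ene <- matrix(0, h, w)
  for (off in glcmOffsets) {
    mp <- .glcmWindowMaps(q, glcmLevels, off, half)
    con <- con + mp$contrast; hom <- hom + mp$homogeneity
    ene <- ene + mp$energy
  }
  nOff <- length(glcmOffsets)
  con <- con / nOff; hom <- hom / nOff; ene <- ene / nOff

  lbp <- lbpMap(image, lbpRadius)

  channels <- array(0, dim = c(7L, h, w))
  channels[1, , ] <- mu
  channels[2, , ] <- med
  channels[3, , ] <- sdm
  channels[4, , ] <- con
  channels[5, , ] <- hom
  channels[6, , ] <- ene
  channels[7, , ] <- lbp / 255
  new("FeatureStack", channels = channels,
      provenance = list(
        intensity = list(descriptor = "local intensity statistics",
                         window = window, channels = c("mean", "median", "sd")),
        glcm = list(descriptor = "GLCM texture", window = window,
                    levels = glcmLevels, offsets = glcmOffsets,
                    channels = c("contrast", "homogeneity", "energy")),
        lbp = list(descriptor = "local binary pattern", radius = lbpRadius,
                   comparison = ">=", channels = "lbp")))
}
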