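#' @include utils.R
NULL

#' Central-difference image gradients
#'
#' `Gx(x, y) = (f(x+1, y) - f(x-1, y)) / 2` along columns and the analogous
#' `Gy` along rows, with replicated borders (so the one-sided difference at
#' the edge is halved).
#'
#' @param image single-channel numeric matrix, at least 3 x 3.
#' @return list with matrices `Gx`, `Gy` of the image's shape.
#' @export
imageGradients <- function(image) {
  if (!is.matrix(image) || nrow(image) < 3L || ncol(image) < 3L)
    stop("degenerate image: need at least 3 x 3")
  Gx <- (.shiftReplicate(image, 1L, 2L) - .shiftReplicate(image, -1L, 2L)) / 2
  Gy <- (.shiftReplicate(image, 1L, 1L) - .shiftReplicate(image, -1L, 1L)) / 2
  list(Gx = Gx, Gy = Gy)
}

#' Construct HOG parameters
#'
#' Canonical defaults: 8-pixel cells, 2 x 2-cell blocks, 9 unsigned
#' orientation bins over \[0, 180) degrees, L2 block normalization with an
#' epsilon guard, hard bin assignment.
#'
#' @param cellSize cell side, pixels.
#' @param blockSize block side, cells.
#' @param nBins number of orientation bins (>= 2).
#' @param signed use the full \[0, 360) range instead of folding to
#'   \[0, 180).
#' @param blockNorm "L2" or "none".
#' @param epsilon normalization guard.
#' @return classed list of HOG parameters.
#' @export
hogParams <- function(cellSize = 8L, blockSize = 2L, nBins = 9L,
                      signed = FALSE, blockNorm = "L2", epsilon = 1e-6) {
  if (nBins < 2L) stop("invalid histogram: nBins must be >= 2")
  if (!blockNorm %in% c("L2", "none")) stop("unknown block norm")
  structure(list(cellSize = as.integer(cellSize),
                 blockSize = as.integer(blockSize),
                 nBins = as.integer(nBins), signed = signed,
                 blockNorm = blockNorm, epsilon = epsilon),
            class = "HOGParams")
}

#' Histogram-of-oriented-gradients features
#'
#' Computes per-pixel gradient magnitude and orientation (folded to
#' \[0, 180) degrees when unsigned), accumulates magnitudes into the angular
#' bin of each pixel's cell (hard assignment), L2-normalizes sliding blocks
#' of cells, and additionally returns per-pixel channel maps in which each
#' cell's raw histogram is broadcast to its pixels (for [featureStack()]
#' use). Pixels beyond the last full cell are attached to the nearest cell in
#' the channel maps and ignored in the cell histograms.
#'
#' @param image single-channel numeric matrix, at least one block large.
#' @param params a [hogParams()] list.
#' @return list with `cellHistograms` (nCellsY x nCellsX x nBins array of
#'   raw, unnormalized histograms), `vector` (concatenated block-normalized
#'   descriptor), and `maps` (nBins x height x width per-pixel channel
#'   array).
#' @export
hogFeatures <- function(image, params = hogParams()) {
  p <- params
  if (p$nBins < 2L) stop("invalid histogram: nBins must be >= 2")
  h <- nrow(image); w <- ncol(image)
  minSide <- p$cellSize * p$blockSize
  if (h < minSide || w < minSide) stop("image smaller than one block")
  g <- imageGradients(image)
  mag <- sqrt(g$Gx^2 + g$Gy^2)
  ang <- atan2(g$Gy, g$Gx) * 180 / pi
  span <- if (p$signed) 360 else 180
  ang <- ang %% span
  binW <- span / p$nBins
  bin <- pmin(floor(ang / binW) + 1L, p$nBins)

  nCy <- h %/% p$cellSize
  nCx <- w %/% p$cellSize
  rows <- matrix(rep(seq_len(h), times = w), h, w)
  cols <- matrix(rep(seq_len(w), each = h), h, w)
  cy <- (rows - 1L) %/% p$cellSize + 1L
  cx <- (cols - 1L) %/% p$cellSize + 1L
  inCells <- cy <= nCy & cx <= nCx
  idx <- (bin - 1L) * (nCy * nCx) + (cx - 1L) * nCy + cy
  acc <- numeric(nCy * nCx * p$nBins)
  sums <- rowsum(as.vector(mag[inCells]), group = as.vector(idx[inCells]))
  acc[as.integer(rownames(sums))] <- sums[, 1]
  hist <- array(acc, dim = c(nCy, nCx, p$nBins))

  ## sliding blocks of blockSize x blockSize cells, stride one cell
  nBy <- nCy - p$blockSize + 1L
  nBx <- nCx - p$blockSize + 1L
  vec <- numeric(0)
  if (nBy >= 1L && nBx >= 1L) {
    blocks <- vector("list", nBy * nBx)
    k <- 0L
    for (by in seq_len(nBy)) {
      for (bx in seq_len(nBx)) {
        v <- as.vector(hist[by:(by + p$blockSize - 1L),
                            bx:(bx + p$blockSize - 1L), ])
        if (p$blockNorm == "L2") v <- v / sqrt(sum(v^2) + p$epsilon^2)
        k <- k + 1L
        blocks[[k]] <- v
      }
    }
    vec <- unlist(blocks, use.names = FALSE)
  }

  ## per-pixel maps: broadcast each cell's raw histogram to its pixels
  cyc <- pmin(cy, nCy); cxc <- pmin(cx, nCx)
  cellIdx <- (cxc - 1L) * nCy + cyc
  maps <- array(0, dim = c(p$nBins, h, w))
  histMat <- matrix(hist, nCy * nCx, p$nBins)
  for (b in seq_len(p$nBins))
    maps[b, , ] <- matrix(histMat[cellIdx, b], h, w)

  list(cellHistograms = hist, vector = vec, maps = maps, params = p)
}
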