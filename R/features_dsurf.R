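#' @include utils.R
NULL

#' Dense keypoint grid
#'
#' Places keypoints on a regular grid: coordinates are
#' `(i * step + margin, j * step + margin)` for all nonnegative integer grid
#' indices that keep the point inside the image with `margin` pixels of
#' support on every side. Coordinates are 0-based, `x` along columns, `y`
#' along rows; keypoints are returned in row-major order (x varies fastest).
#' An over-restrictive margin yields an empty grid, not an error.
#'
#' @param width,height image extent in pixels.
#' @param step grid step in pixels (>= 1).
#' @param margin support margin in pixels.
#' @return data.frame with columns `x`, `y`.
#' @export
denseGrid <- function(width, height, step, margin = 0L) {
  if (step < 1) stop("step must be >= 1")
  if (margin > width - 1 - margin || margin > height - 1 - margin)
    return(data.frame(x = integer(0), y = integer(0)))
  xs <- seq(margin, width - 1 - margin, by = step)
  ys <- seq(margin, height - 1 - margin, by = step)
  data.frame(x = rep(xs, times = length(ys)),
             y = rep(ys, each = length(xs)))
}

# Gaussian first-derivative response maps at scale sigma
.gaussDerivResponses <- function(image, sigma) {
  g <- .gaussKernel(sigma)
  d <- .gaussDerivKernel(sigma)
  list(Lx = .sepFilter(image, g, d),   # derivative along x (columns)
       Ly = .sepFilter(image, d, g))   # derivative along y (rows)
}

#' Second-order Gaussian-derivative (Hessian) responses
#'
#' Returns the three distinct entries of the Hessian of the image smoothed at
#' scale `sigma` (Lxy stored once; the matrix is symmetric). Provided for
#' diagnostics; the dense grid replaces interest-point detection, so nothing
#' downstream consumes these by default.
#'
#' @param image numeric matrix.
#' @param sigma derivative scale.
#' @return list with full-resolution maps `Lxx`, `Lxy`, `Lyy` and `sigma`.
#' @export
hessianResponses <- function(image, sigma = 1.6) {
  g <- .gaussKernel(sigma)
  d1 <- .gaussDerivKernel(sigma)
  d2 <- .gaussDeriv2Kernel(sigma)
  list(Lxx = .sepFilter(image, g, d2),
       Lxy = .sepFilter(image, d1, d1),
       Lyy = .sepFilter(image, d2, g),
       sigma = sigma)
}

#' Dense SURF descriptors
#'
#' Computes 64-dimensional SURF-style descriptors on a dense grid. At every
#' grid keypoint, Gaussian first-derivative responses (dx, dy) are collected
#' over a square support window, the window is partitioned into 4 x 4
#' sub-regions, and each sub-region contributes the tuple
#' (sum dx, sum dy, sum |dx|, sum |dy|), giving 4 x 4 x 4 = 64 ordered values
#' which are then L2-normalized (zero descriptors stay zero).
#'
#' With `oriented = TRUE`, a dominant orientation
#' `theta = atan2(sum W dx, sum W dy)` is first estimated over a Gaussian
#' weight `W` on the support window, and the responses are resampled in the
#' rotated frame so the descriptor is orientation-aligned. The dense-grid
#' pipeline does not require orientation, so it is off by default.
#'
#' Keypoints whose support window leaves the image are skipped; their number
#' is recorded in the `skipped` field.
#'
#' @param image single-channel numeric matrix.
#' @param step grid step in pixels.
#' @param sigma Gaussian derivative scale.
#' @param window support window side in pixels, divisible by 4.
#' @param oriented estimate and align to a dominant orientation.
#' @return list with `keypoints` (data.frame x, y, scale), `orientations`
#'   (radians, 0 when `oriented = FALSE`), `descriptors` (n x 64 matrix) and
#'   `skipped` (count of keypoints without full support).
#' @export
dsurfDescriptors <- function(image, step = 8L, sigma = 1.6, window = 16L,
                             oriented = FALSE) {
  if (!is.matrix(image)) stop("single-channel image required")
  if (window %% 4 != 0) stop("window must be divisible by 4")
  h <- nrow(image); w <- ncol(image)
  kp <- denseGrid(w, h, step)
  resp <- .gaussDerivResponses(image, sigma)
  half <- window %/% 2L
  sub <- window %/% 4L
  # sub-region index (row-major over the 4 x 4 partition) for every window px
  subIdx <- matrix(0L, window, window)
  for (r in seq_len(window)) for (cc in seq_len(window))
    subIdx[r, cc] <- ((r - 1L) %/% sub) * 4L + ((cc - 1L) %/% sub) + 1L
  wGauss <- outer(stats::dnorm(seq_len(window) - half - 0.5, sd = window / 4),
                  stats::dnorm(seq_len(window) - half - 0.5, sd = window / 4))

  desc <- matrix(0, nrow(kp), 64L)
  theta <- numeric(nrow(kp))
  keep <- logical(nrow(kp))
  for (i in seq_len(nrow(kp))) {
    cx <- kp$x[i] + 1L; cy <- kp$y[i] + 1L   # 1-based center
    rows <- (cy - half + 1L):(cy + half)
    cols <- (cx - half + 1L):(cx + half)
    if (rows[1] < 1L || cols[1] < 1L || rows[window] > h || cols[window] > w)
      next
    keep[i] <- TRUE
    if (!oriented) {
      dx <- resp$Lx[rows, cols]
      dy <- resp$Ly[rows, cols]
    } else {
      dx0 <- resp$Lx[rows, cols]
      dy0 <- resp$Ly[rows, cols]
      th <- atan2(sum(wGauss * dx0), sum(wGauss * dy0))
      theta[i] <- th
      # sample responses in the frame rotated by theta about the keypoint
      u <- rep(seq_len(window) - half - 0.5, each = window)   # x offsets
      v <- rep(seq_len(window) - half - 0.5, times = window)  # y offsets
      xs <- cx + cos(th) * u - sin(th) * v
      ys <- cy + sin(th) * u + cos(th) * v
      lx <- .sampleBilinear(resp$Lx, xs, ys)
      ly <- .sampleBilinear(resp$Ly, xs, ys)
      # rotate the gradient vectors into the aligned frame
      dxv <- cos(th) * lx + sin(th) * ly
      dyv <- -sin(th) * lx + cos(th) * ly
      dx <- matrix(dxv, window, window)   # x varies slowly = columns
      dy <- matrix(dyv, window, window)
    }
    v64 <- numeric(64)
    for (s in 1:16) {
      m <- subIdx == s
      v64[(s - 1L) * 4L + 1L] <- sum(dx[m])
      v64[(s - 1L) * 4L + 2L] <- sum(dy[m])
      v64[(s - 1L) * 4L + 3L] <- sum(abs(dx[m]))
      v64[(s - 1L) * 4L + 4L] <- sum(abs(dy[m]))
    }
    nrm <- sqrt(sum(v64^2))
    # normalization guard: descriptors below numerical noise are exactly zero
    v64 <- if (nrm > 1e-12) v64 / nrm else numeric(64L)
    desc[i, ] <- v64
  }
  list(keypoints = data.frame(kp[keep, , drop = FALSE], scale = sigma,
                              row.names = NULL),
       orientations = theta[keep],
       descriptors = desc[keep, , drop = FALSE],
       skipped = sum(!keep),
       step = step, window = window)
}
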