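# Low-level image primitives shared by the feature extractors, the phantom
# generator and the augmentation module. Coordinate convention throughout:
# x = column, y = row; matrices are indexed [row, col] = [y, x].

#' @importFrom stats rnorm runif ecdf median sd
NULL

## --- separable filtering -----------------------------------------------

# 1-D shift with replicated borders, along rows (dim=1) or cols (dim=2)
.shiftReplicate <- function(m, offset, dim) {
  n <- dim(m)[dim]
  idx <- pmin(pmax(seq_len(n) + offset, 1L), n)
  if (dim == 1L) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
}

# separable convolution with 1-D kernels (replicated borders); kernel taps
# are centered: tap i corresponds to offset i - (length+1)/2
.sepFilter <- function(m, kRow, kCol) {
  out <- m
  if (!is.null(kCol)) {
    half <- (length(kCol) + 1L) %/% 2L
    acc <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(kCol))
      acc <- acc + kCol[i] * .shiftReplicate(out, i - half, 2L)
    out <- acc
  }
  if (!is.null(kRow)) {
    half <- (length(kRow) + 1L) %/% 2L
    acc <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(kRow))
      acc <- acc + kRow[i] * .shiftReplicate(out, i - half, 1L)
    out <- acc
  }
  out
}

.gaussKernel <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# first derivative of a Gaussian, normalized so that a unit ramp maps to 1
.gaussDerivKernel <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq(-radius, radius)
  k <- -x * exp(-x^2 / (2 * sigma^2))
  s <- sum(k * x)             # response of k to the ramp f = x
  k / s
}

# second derivative of a Gaussian (for Hessian responses), normalized so
# that f = x^2/2 maps to 1
.gaussDeriv2Kernel <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq(-radius, radius)
  k <- (x^2 / sigma^2 - 1) * exp(-x^2 / (2 * sigma^2))
  k <- k - mean(k)            # zero response to constants
  s <- sum(k * x^2 / 2)
  k / s
}

.gaussianBlur <- function(m, sigma) {
  k <- .gaussKernel(sigma)
  .sepFilter(m, k, k)
}

## --- resampling --------------------------------------------------------

# bilinear sample of matrix m at (x, y) (1-based, x = col); outside -> 0
.sampleBilinear <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;  fy <- y - y0
  val <- numeric(length(x))
  gather <- function(xi, yi) {
    ok <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
    v <- numeric(length(xi))
    v[ok] <- m[cbind(yi[ok], xi[ok])]
    v
  }
  val <- gather(x0, y0) * (1 - fx) * (1 - fy) +
         gather(x0 + 1, y0) * fx * (1 - fy) +
         gather(x0, y0 + 1) * (1 - fx) * fy +
         gather(x0 + 1, y0 + 1) * fx * fy
  val
}

# nearest-neighbor sample; outside -> fill (labels stay in the input set)
.sampleNearest <- function(m, x, y, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  xi <- round(x); yi <- round(y)
  ok <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
  v <- rep(fill, length(x))
  v[ok] <- m[cbind(yi[ok], xi[ok])]
  v
}

## --- intensity ---------------------------------------------------------

# global histogram equalization onto [0,1] via the empirical CDF;
# constant input maps to all zeros
.histEqualize <- function(v) {
  cdf <- ecdf(as.vector(v))(v)
  lo <- min(cdf)
  if (1 - lo < 1e-12) return(v * 0)
  (cdf - lo) / (1 - lo)
}

## --- seeding -----------------------------------------------------------

# deterministic per-item seed derived from (seed, index); kept < 2^31 and
# exact in double arithmetic
.deriveSeed <- function(seed, index) {
  m <- 2147483563
  as.integer((((seed %% m) * 69069 + (index %% m) * 104729 + 17) %% m))
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
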