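# brute-force HOG oracle: per-pixel gradient, bin, accumulate, normalize;
# shared by the HOG unit tests and the acceptance checks
hogOracle <- function(image, cell = 8L, block = 2L, nBins = 9L,
                      eps = 1e-6) {
  h <- nrow(image); w <- ncol(image)
  Gx <- matrix(0, h, w); Gy <- matrix(0, h, w)
  for (r in 1:h) for (cc in 1:w) {
    Gx[r, cc] <- (image[r, min(cc + 1, w)] - image[r, max(cc - 1, 1)]) / 2
    Gy[r, cc] <- (image[min(r + 1, h), cc] - image[max(r - 1, 1), cc]) / 2
  }
  nCy <- h %/% cell; nCx <- w %/% cell
  hist <- array(0, dim = c(nCy, nCx, nBins))
  for (r in 1:h) for (cc in 1:w) {
    cy <- (r - 1) %/% cell + 1; cx <- (cc - 1) %/% cell + 1
    if (cy > nCy || cx > nCx) next
    mag <- sqrt(Gx[r, cc]^2 + Gy[r, cc]^2)
    ang <- (atan2(Gy[r, cc], Gx[r, cc]) * 180 / pi) %% 180
    b <- min(floor(ang / (180 / nBins)) + 1, nBins)
    hist[cy, cx, b] <- hist[cy, cx, b] + mag
  }
  vec <- c()
  for (by in 1:(nCy - block + 1)) for (bx in 1:(nCx - block + 1)) {
    v <- as.vector(hist[by:(by + block - 1), bx:(bx + block - 1), ])
    vec <- c(vec, v / sqrt(sum(v^2) + eps^2))
  }
  list(hist = hist, vec = vec)
}
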