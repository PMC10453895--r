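# brute-force pair-enumeration oracle for the co-occurrence matrix
glcmOracle <- function(q, levels, offset, symmetric = TRUE) {
  G <- matrix(0, levels, levels)
  h <- nrow(q); w <- ncol(q)
  for (r in 1:h) for (cc in 1:w) {
    r2 <- r + offset[1]; c2 <- cc + offset[2]
    if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
    G[q[r, cc] + 1, q[r2, c2] + 1] <- G[q[r, cc] + 1, q[r2, c2] + 1] + 1
  }
  if (symmetric) G <- G + t(G)
  G
}

test_that("GLCM matches brute-force pair enumeration and normalizes to 1", {
  m <- rbind(c(0, 0), c(1, 1))
  G <- glcmMatrix(m, levels = 2L, offset = c(0L, 1L), normalize = FALSE)
  expect_equal(G, matrix(c(2, 0, 0, 2), 2, 2))
  Gn <- glcmMatrix(m, levels = 2L, offset = c(0L, 1L))
  expect_equal(Gn, matrix(c(0.5, 0, 0, 0.5), 2, 2))

  set.seed(31)
  for (rep in 1:20) {
    img <- matrix(runif(8 * 8), 8, 8)
    off <- sample(list(c(0L, 1L), c(1L, 0L), c(1L, 1L)), 1)[[1]]
    G <- glcmMatrix(img, levels = 4L, offset = off, normalize = FALSE)
    q <- pmin(floor(img * 4), 3)
    expect_equal(G, glcmOracle(q, 4L, off))
    Gn <- glcmMatrix(img, levels = 4L, offset = off)
    expect_equal(sum(Gn), 1)
    expect_equal(Gn, t(Gn))
  }
  expect_error(glcmMatrix(m, levels = 1L), "invalid quantization")
})

test_that("checkerboard contrast is maximal among 2-level images", {
  board <- outer(1:2, 1:4, function(r, cc) (r + cc) %% 2)
  contrastOf <- function(img) {
    G <- glcmMatrix(img, levels = 2L, offset = c(0L, 1L))
    sum(G * outer(0:1, 0:1, function(a, b) (a - b)^2))
  }
  cBoard <- contrastOf(board)
  # exhaustive comparison over all 2-level images of the same column count
  combos <- expand.grid(rep(list(0:1), 8))
  for (i in seq_len(nrow(combos))) {
    img <- matrix(as.numeric(combos[i, ]), 2, 4)
    expect_lte(contrastOf(img), cBoard + 1e-12)
  }
  expect_equal(cBoard, 1)
})

test_that("constant images give the degenerate texture features", {
  cst <- matrix(0.4, 16, 16)
  fs <- textureIntensityMaps(cst)
  ch <- stackChannels(fs)
  expect_equal(ch[1, , ], matrix(0.4, 16, 16))          # mean
  expect_equal(ch[2, , ], matrix(0.4, 16, 16))          # median
  expect_true(all(abs(ch[3, , ]) < 1e-7))               # sd
  expect_true(all(ch[4, , ] == 0))                      # contrast
  expect_true(all(ch[5, , ] == 1))                      # homogeneity
  expect_true(all(ch[6, , ] == 1))                      # energy
  expect_true(all(ch[7, , ] == 1))                      # LBP 255/255
  expect_equal(lbpMap(cst)[3, 3], 255)
})

test_that("sliding-window statistics match direct window computation", {
  set.seed(32)
  img <- matrix(runif(12 * 12), 12, 12)
  fs <- textureIntensityMaps(img, window = 5L)
  ch <- stackChannels(fs)
  for (pt in list(c(1, 1), c(3, 7), c(6, 6), c(12, 12))) {
    r <- pt[1]; cc <- pt[2]
    rows <- max(1, r - 2):min(12, r + 2)
    cols <- max(1, cc - 2):min(12, cc + 2)
    win <- img[rows, cols]
    expect_equal(ch[1, r, cc], mean(win), tolerance = 1e-12)
    expect_equal(ch[2, r, cc], median(win), tolerance = 1e-12)
    expect_equal(ch[3, r, cc], sqrt(mean((win - mean(win))^2)),
                 tolerance = 1e-10)
  }
  expect_error(textureIntensityMaps(img, window = 4L), "window must be odd")
  expect_error(textureIntensityMaps(img, glcmLevels = 1L),
               "invalid quantization")
})

test_that("windowed GLCM energy agrees with the explicit matrix on one window", {
  set.seed(33)
  img <- matrix(runif(9 * 9), 9, 9)
  fs <- textureIntensityMaps(img, window = 9L, glcmLevels = 4L,
                             glcmOffsets = list(c(0L, 1L)))
  ch <- stackChannels(fs)
  # the center pixel's window is the whole image; compare against glcmMatrix
  G <- glcmMatrix(img, levels = 4L, offset = c(0L, 1L))
  lv <- outer(0:3, 0:3, function(a, b) (a - b)^2)
  expect_equal(ch[4, 5, 5], sum(G * lv), tolerance = 1e-12)
  expect_equal(ch[5, 5, 5], sum(G / (1 + lv)), tolerance = 1e-12)
  expect_equal(ch[6, 5, 5], sum(G^2), tolerance = 1e-12)
})

test_that("LBP codes encode neighbor-vs-center comparisons", {
  m <- matrix(0, 3, 3)
  m[2, 2] <- 1              # center above all neighbors -> code 0
  expect_equal(lbpMap(m)[2, 2], 0)
  m2 <- matrix(0, 3, 3)
  m2[2, 2] <- 0.5; m2[2, 3] <- 1   # exactly one neighbor at/above center
  expect_true(lbpMap(m2)[2, 2] > 0 && lbpMap(m2)[2, 2] < 255)
  expect_true(all(lbpMap(matrix(runif(25), 5, 5)) %in% 0:255))
})

test_that("feature stacks align channels and validate inputs", {
  pair <- makeTestSlicePair(side = 64L)
  img <- matrix(pixelData(pair$slice)[4, , ], 64, 64)
  ds <- dsurfDescriptors(img, step = 8L, window = 16L)
  hf <- hogFeatures(img)
  tx <- textureIntensityMaps(img)
  fs <- featureStack(c(64, 64), dsurf = ds, hog = hf, texture = tx)
  expect_equal(nChannels(fs), 64L + 9L + 7L)
  expect_true(all(is.finite(stackChannels(fs))))
  expect_named(fs@provenance)

  fsHog <- featureStack(c(64, 64), hog = hf)
  expect_equal(nChannels(fsHog), 9L)
  expect_equal(dim(stackChannels(fsHog))[2:3], c(64L, 64L))
  expect_error(featureStack(c(64, 64)), "unaligned features")

  # DSURF channels are piecewise constant on the nearest-keypoint cells
  fsD <- featureStack(c(64, 64), dsurf = ds)
  ys <- sort(unique(ds$keypoints$y)) + 1
  ch1 <- stackChannels(fsD)[1, , ]
  for (kyi in seq_along(ys)[-1]) {
    lo <- ys[kyi] - 3; hi <- ys[kyi] + 3   # strictly nearest rows
    expect_true(all(apply(ch1[lo:hi, ], 2, function(v) length(unique(v)) == 1)))
  }
  # channel subset selection
  fsSub <- featureStack(c(64, 64), dsurf = ds, dsurfChannels = c(1, 3, 5))
  expect_equal(nChannels(fsSub), 3L)
})

test_that("extractFeatures wires slice channels into a stack", {
  pair <- makeTestSlicePair(side = 64L)
  fs <- extractFeatures(pair$slice, features = c("hog", "texture"))
  expect_equal(nChannels(fs), 16L)
  expect_equal(dim(stackChannels(fs))[2:3], c(64L, 64L))
})
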