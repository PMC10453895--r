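# Minimal CNN engine on base BLAS. Tensors are 4-D arrays laid out
# (height, width, batch, channel); convolutions are evaluated as one matrix
# multiplication per kernel tap (shift-and-multiply), which keeps both the
# forward and the backward pass inside optimized GEMM calls.

.pad2 <- function(X, pad) {
  if (pad == 0L) return(X)
  d <- dim(X)
  Xp <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  Xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- X
  Xp
}

# W: (kh, kw, Cin, Cout), b: length Cout; 'same' zero padding, stride 1
.convForward <- function(X, W, b) {
  d <- dim(X); H <- d[1]; Wd <- d[2]; N <- d[3]; Cin <- d[4]
  kd <- dim(W); kh <- kd[1]; kw <- kd[2]; Cout <- kd[4]
  pad <- (kh - 1L) %/% 2L
  Xp <- .pad2(X, pad)
  acc <- matrix(0, H * Wd * N, Cout)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      Xs <- Xp[i:(i + H - 1L), j:(j + Wd - 1L), , , drop = FALSE]
      dim(Xs) <- c(H * Wd * N, Cin)
      acc <- acc + Xs %*% matrix(W[i, j, , ], Cin, Cout)
    }
  }
  acc <- acc + rep(b, each = H * Wd * N)
  dim(acc) <- c(H, Wd, N, Cout)
  acc
}

.convBackward <- function(X, W, dY) {
  d <- dim(X); H <- d[1]; Wd <- d[2]; N <- d[3]; Cin <- d[4]
  kd <- dim(W); kh <- kd[1]; kw <- kd[2]; Cout <- kd[4]
  pad <- (kh - 1L) %/% 2L
  Xp <- .pad2(X, pad)
  dYm <- dY; dim(dYm) <- c(H * Wd * N, Cout)
  dW <- array(0, dim = kd)
  dXp <- array(0, dim = dim(Xp))
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      Xs <- Xp[i:(i + H - 1L), j:(j + Wd - 1L), , , drop = FALSE]
      dim(Xs) <- c(H * Wd * N, Cin)
      dW[i, j, , ] <- crossprod(Xs, dYm)
      dXs <- dYm %*% t(matrix(W[i, j, , ], Cin, Cout))
      dim(dXs) <- c(H, Wd, N, Cin)
      dXp[i:(i + H - 1L), j:(j + Wd - 1L), , ] <-
        dXp[i:(i + H - 1L), j:(j + Wd - 1L), , , drop = FALSE] + dXs
    }
  }
  dX <- dXp[pad + seq_len(H), pad + seq_len(Wd), , , drop = FALSE]
  list(dX = dX, dW = dW, db = colSums(dYm))
}

.reluForward <- function(X) {
  Y <- X
  Y[Y < 0] <- 0
  Y
}

.reluBackward <- function(X, dY) dY * (X > 0)

# 2x2 max pooling, stride 2; gradient routed to the first maximum in the
# fixed order (top-left, top-right, bottom-left, bottom-right)
.maxPoolForward <- function(X) {
  d <- dim(X)
  ro <- seq(1L, d[1], by = 2L); re <- ro + 1L
  co <- seq(1L, d[2], by = 2L); ce <- co + 1L
  a <- X[ro, co, , , drop = FALSE]; b <- X[ro, ce, , , drop = FALSE]
  cc <- X[re, co, , , drop = FALSE]; dd <- X[re, ce, , , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  m1 <- a == m
  m2 <- (b == m) & !m1
  m3 <- (cc == m) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  list(Y = m, masks = list(m1, m2, m3, m4))
}

.maxPoolBackward <- function(dY, masks, inDim) {
  dX <- array(0, dim = inDim)
  ro <- seq(1L, inDim[1], by = 2L); re <- ro + 1L
  co <- seq(1L, inDim[2], by = 2L); ce <- co + 1L
  dX[ro, co, , ] <- dY * masks[[1]]
  dX[ro, ce, , ] <- dY * masks[[2]]
  dX[re, co, , ] <- dY * masks[[3]]
  dX[re, ce, , ] <- dY * masks[[4]]
  dX
}

# 2x nearest-neighbor upsampling
.upsampleForward <- function(X) {
  d <- dim(X)
  X[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

.upsampleBackward <- function(dY) {
  d <- dim(dY)
  ro <- seq(1L, d[1], by = 2L); re <- ro + 1L
  co <- seq(1L, d[2], by = 2L); ce <- co + 1L
  dY[ro, co, , , drop = FALSE] + dY[ro, ce, , , drop = FALSE] +
    dY[re, co, , , drop = FALSE] + dY[re, ce, , , drop = FALSE]
}

# 2x average pooling, applied 'times' times (feature-map fusion downsampling)
.avgPoolTimes <- function(X, times) {
  for (k in seq_len(times)) {
    d <- dim(X)
    ro <- seq(1L, d[1], by = 2L); re <- ro + 1L
    co <- seq(1L, d[2], by = 2L); ce <- co + 1L
    X <- (X[ro, co, , , drop = FALSE] + X[ro, ce, , , drop = FALSE] +
          X[re, co, , , drop = FALSE] + X[re, ce, , , drop = FALSE]) / 4
  }
  X
}

.concatC <- function(A, B) {
  da <- dim(A); db <- dim(B)
  array(c(A, B), dim = c(da[1], da[2], da[3], da[4] + db[4]))
}

# softmax over the channel dimension
.softmaxC <- function(X) {
  d <- dim(X)
  M <- X; dim(M) <- c(d[1] * d[2] * d[3], d[4])
  M <- M - apply(M, 1, max)
  E <- exp(M)
  P <- E / rowSums(E)
  dim(P) <- d
  P
}
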