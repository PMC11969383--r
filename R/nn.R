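# Volumetric conv-net layer engine.
#
# Activations for a batch of N single-channel volumes are stored as a
# dense matrix of shape (S*N) x C, where S = prod(spatial dims), rows are
# sample-major (row = (n-1)*S + s) and s runs over (Z, Y, X) column-major.
# Convolutions are im2col patch gathers (C kernels, see src/) followed by
# one BLAS GEMM; the input gradient comes either from scattering dy W^T
# back onto the grid (col2im) or from correlating dy with the flipped,
# channel-transposed kernel, whichever moves fewer values. Large patch
# buffers are preallocated per layer and reused across steps.
#
# Everything here is deterministic given the R RNG state; dropout is the
# only stochastic layer.

.nnCache <- new.env(parent = emptyenv())

# drop all cached patch buffers (called after a training run so large
# reusable buffers do not outlive the model that needed them)
.nnClearBuffers <- function() rm(list = ls(.nnCache), envir = .nnCache)

# preallocated numeric matrix buffer (training hot path); a buffer is only
# valid until the same key's next use, which the step structure guarantees
.nnBuf <- function(key, nr, nc) {
  b <- .nnCache[[key]]
  if (is.null(b) || nrow(b) != nr || ncol(b) != nc) {
    b <- matrix(0, nr, nc)
    .nnCache[[key]] <- b
  }
  b
}

# im2col patch matrix for the 3x3(x3) window, zero padding 1.
# x: (S*N) x C; result: (S*N) x (K*C), columns ordered (ci-1)*K + k with
# the offset index k running (dz,)dy,dx lexicographically, dz/dy fastest.
.nnIm2col <- function(x, spdim, N, bufKey = NULL) {
  C <- ncol(x)
  S <- prod(spdim)
  nd3 <- length(spdim) == 3L
  K <- if (nd3) 27L else 9L
  P <- if (is.null(bufKey)) matrix(0, S * N, K * C)
       else .nnBuf(paste0(bufKey, "_", S * N, "x", K * C), S * N, K * C)
  if (nd3) cpp_im2col3(x, as.integer(spdim), N, C, P)
  else cpp_im2col2(x, as.integer(spdim), N, C, P)
  P
}

# W: (K*Cin) x Cout, rows ordered (ci-1)*K + k
.nnConvFwd <- function(x, W, bias, spdim, N, keep, tag = NULL) {
  P <- .nnIm2col(x, spdim, N,
                 bufKey = if (is.null(tag)) NULL else paste0(tag, "_f"))
  y <- P %*% W
  if (!is.null(bias)) y <- y + rep(bias, each = nrow(y))
  list(y = y, P = if (keep) P else NULL)
}

.nnConvBwd <- function(dy, W, P, spdim, N, tag = NULL) {
  nd3 <- length(spdim) == 3L
  K <- if (nd3) 27L else 9L
  Cin <- ncol(P) %/% K
  Cout <- ncol(dy)
  S <- prod(spdim)
  dW <- crossprod(P, dy)
  db <- colSums(dy)
  if (Cin <= Cout) {
    # adjoint route: dP = dy W^T, scattered back onto the grid (col2im);
    # moves K*Cin values per voxel instead of K*Cout
    dP <- dy %*% t(W)
    acc <- matrix(0, S * N, Cin)
    dx <- if (nd3) cpp_col2im3(dP, as.integer(spdim), N, Cin, acc)
          else cpp_col2im2(dP, as.integer(spdim), N, Cin, acc)
  } else {
    # correlation route: gather dy patches, multiply by the flipped,
    # channel-transposed kernel
    P2 <- .nnIm2col(dy, spdim, N,
                    bufKey = if (is.null(tag)) NULL else paste0(tag, "_b"))
    arrW <- array(W, c(K, Cin, Cout))
    Wb <- matrix(aperm(arrW[K:1, , , drop = FALSE], c(1, 3, 2)),
                 K * Cout, Cin)
    dx <- P2 %*% Wb
  }
  list(dx = dx, dW = dW, db = db)
}

# channel-group normalization over (spatial x channels-in-group), per sample
.nnGnFwd <- function(x, gamma, beta, ngroups, S, N, eps = 1e-5) {
  C <- ncol(x)
  Cg <- C %/% ngroups
  y <- x
  xhat <- x
  invstd <- matrix(0, N, ngroups)
  for (gi in seq_len(ngroups)) {
    cols <- (gi - 1L) * Cg + seq_len(Cg)
    sub <- x[, cols, drop = FALSE]
    M <- matrix(sub, S, N * Cg)
    cm <- .colMeans(M, S, N * Cg)
    mu <- rowMeans(matrix(cm, N, Cg))
    cm2 <- .colMeans(M * M, S, N * Cg)
    vr <- rowMeans(matrix(cm2, N, Cg)) - mu^2
    istd <- 1 / sqrt(vr + eps)
    xh <- (sub - rep(mu, each = S)) * rep(istd, each = S)
    xhat[, cols] <- xh
    y[, cols] <- xh * rep(gamma[cols], each = S * N) +
      rep(beta[cols], each = S * N)
    invstd[, gi] <- istd
  }
  list(y = y, xhat = xhat, invstd = invstd)
}

.nnGnBwd <- function(dy, cache, gamma, ngroups, S, N) {
  C <- ncol(dy)
  Cg <- C %/% ngroups
  dx <- dy
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  for (gi in seq_len(ngroups)) {
    cols <- (gi - 1L) * Cg + seq_len(Cg)
    xh <- cache$xhat[, cols, drop = FALSE]
    dxh <- dy[, cols, drop = FALSE] * rep(gamma[cols], each = S * N)
    m1 <- rowMeans(matrix(.colMeans(matrix(dxh, S, N * Cg), S, N * Cg),
                          N, Cg))
    m2 <- rowMeans(matrix(.colMeans(matrix(dxh * xh, S, N * Cg), S, N * Cg),
                          N, Cg))
    dx[, cols] <- (dxh - rep(m1, each = S) - xh * rep(m2, each = S)) *
      rep(cache$invstd[, gi], each = S)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# 2x2(x2) max pooling, stride 2, floor semantics (odd trailing planes drop)
.nnPoolFwd <- function(x, spdim, N) {
  C <- ncol(x)
  nd <- length(spdim)
  d2 <- spdim %/% 2L
  if (nd == 3L) {
    arr <- array(x, c(spdim, N, C))
    arr <- arr[seq_len(2L * d2[1]), seq_len(2L * d2[2]),
               seq_len(2L * d2[3]), , , drop = FALSE]
    dim(arr) <- c(2L, d2[1], 2L, d2[2], 2L, d2[3], N, C)
    pa <- aperm(arr, c(2, 4, 6, 7, 8, 1, 3, 5))
    nslot <- 8L
  } else {
    arr <- array(x, c(spdim, N, C))
    arr <- arr[seq_len(2L * d2[1]), seq_len(2L * d2[2]), , , drop = FALSE]
    dim(arr) <- c(2L, d2[1], 2L, d2[2], N, C)
    pa <- aperm(arr, c(2, 4, 5, 6, 1, 3))
    nslot <- 4L
  }
  m <- matrix(pa, prod(d2) * N * C, nslot)
  best <- m[, 1]
  wh <- rep(1L, nrow(m))
  for (k in 2:nslot) {  # first-maximum tie routing
    upd <- m[, k] > best
    best[upd] <- m[upd, k]
    wh[upd] <- k
  }
  list(y = matrix(best, prod(d2) * N, C), wh = wh, d2 = d2,
       spdimIn = spdim, nslot = nslot)
}

.nnPoolBwd <- function(dy, cache, N) {
  C <- ncol(dy)
  d2 <- cache$d2
  spdim <- cache$spdimIn
  nd <- length(spdim)
  v <- as.vector(dy)
  gmat <- matrix(0, length(v), cache$nslot)
  gmat[cbind(seq_along(v), cache$wh)] <- v
  if (nd == 3L) {
    pa <- array(gmat, c(d2, N, C, 2L, 2L, 2L))
    arr <- aperm(pa, c(6, 1, 7, 2, 8, 3, 4, 5))
    dim(arr) <- c(2L * d2, N, C)
    full <- array(0, c(spdim, N, C))
    full[seq_len(2L * d2[1]), seq_len(2L * d2[2]), seq_len(2L * d2[3]), , ] <-
      arr
  } else {
    pa <- array(gmat, c(d2, N, C, 2L, 2L))
    arr <- aperm(pa, c(5, 1, 6, 2, 3, 4))
    dim(arr) <- c(2L * d2, N, C)
    full <- array(0, c(spdim, N, C))
    full[seq_len(2L * d2[1]), seq_len(2L * d2[2]), , ] <- arr
  }
  matrix(full, prod(spdim) * N, C)
}

# global (adaptive output size 1) max pooling: (S*N) x C -> N x C
.nnGlobalMaxFwd <- function(x, S, N) {
  C <- ncol(x)
  arr <- matrix(x, S, N * C)
  best <- arr[1, ]
  wh <- rep(1L, N * C)
  if (S > 1L) for (s in 2:S) {
    v <- arr[s, ]
    upd <- v > best
    best[upd] <- v[upd]
    wh[upd] <- s
  }
  list(y = matrix(best, N, C), wh = wh)
}

.nnGlobalMaxBwd <- function(dy, cache, S, N) {
  C <- ncol(dy)
  dx <- matrix(0, S * N, C)
  n <- rep(seq_len(N), C)
  cc <- rep(seq_len(C), each = N)
  rows <- (n - 1L) * S + cache$wh
  dx[cbind(rows, cc)] <- as.vector(dy)
  dx
}
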