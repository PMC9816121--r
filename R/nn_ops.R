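# Low-level differentiable layer primitives for the embedding U-Net.
#
# Feature maps for a batch are stored as a (B * H * W) x C matrix: samples
# stacked in row blocks, pixels within a slice in column-major order (first
# in-plane axis fastest). Convolution gathers/scatters run in C++
# (cpp_im2col3x3 / cpp_col2im3x3); all matrix products go through BLAS.
# Every *_bwd returns exact gradients of its *_fwd; the composition is
# verified against finite differences in the test suite.

conv3x3_init <- function(c_in, c_out) {
  list(W = matrix(rnorm(9L * c_in * c_out, sd = sqrt(2 / (9 * c_in))),
                  nrow = 9L * c_in, ncol = c_out),
       b = numeric(c_out))
}

conv3x3_fwd <- function(X, par, B, H, W) {
  Xcol <- cpp_im2col3x3(X, B, H, W)
  out <- Xcol %*% par$W
  out <- sweep(out, 2L, par$b, "+")
  list(out = out, cache = Xcol)
}

conv3x3_bwd <- function(dY, par, cache, B, H, W) {
  list(dX = cpp_col2im3x3(dY %*% t(par$W), B, H, W,
                          nrow(par$W) %/% 9L),
       dW = crossprod(cache, dY),
       db = colSums(dY))
}

conv1x1_init <- function(c_in, c_out) {
  list(W = matrix(rnorm(c_in * c_out, sd = sqrt(2 / c_in)), c_in, c_out),
       b = numeric(c_out))
}

conv1x1_fwd <- function(X, par) {
  list(out = sweep(X %*% par$W, 2L, par$b, "+"), cache = X)
}

conv1x1_bwd <- function(dY, par, cache) {
  list(dX = dY %*% t(par$W), dW = crossprod(cache, dY), db = colSums(dY))
}

gn_init <- function(c) list(gamma = rep(1, c), beta = numeric(c))

# per-sample, per-group normalization over (HW x channels-in-group) elements
gn_fwd <- function(X, par, B, HW, groups, eps = 1e-5) {
  C <- ncol(X)
  k <- C %/% groups
  xhat <- X
  invstd <- matrix(0, B, groups)
  for (g in seq_len(groups)) {
    idx <- ((g - 1L) * k + 1L):(g * k)
    Xg <- X[, idx, drop = FALSE]
    m <- HW * k
    s1 <- rowSums(matrix(colSums(matrix(Xg, nrow = HW)), nrow = B))
    s2 <- rowSums(matrix(colSums(matrix(Xg * Xg, nrow = HW)), nrow = B))
    mu <- s1 / m
    istd <- 1 / sqrt(pmax(s2 / m - mu^2, 0) + eps)
    xhat[, idx] <- (Xg - rep(mu, each = HW)) * rep(istd, each = HW)
    invstd[, g] <- istd
  }
  out <- sweep(sweep(xhat, 2L, par$gamma, "*"), 2L, par$beta, "+")
  list(out = out, cache = list(xhat = xhat, invstd = invstd))
}

gn_bwd <- function(dY, par, cache, B, HW, groups) {
  C <- ncol(dY)
  k <- C %/% groups
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dX <- matrix(0, nrow(dY), C)
  for (g in seq_len(groups)) {
    idx <- ((g - 1L) * k + 1L):(g * k)
    dxh <- sweep(dY[, idx, drop = FALSE], 2L, par$gamma[idx], "*")
    xh <- xhat[, idx, drop = FALSE]
    m <- HW * k
    m1 <- rowSums(matrix(colSums(matrix(dxh, nrow = HW)), nrow = B)) / m
    m2 <- rowSums(matrix(colSums(matrix(dxh * xh, nrow = HW)), nrow = B)) / m
    dX[, idx] <- rep(cache$invstd[, g], each = HW) *
      (dxh - rep(m1, each = HW) - xh * rep(m2, each = HW))
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(X) {
  out <- X * (X > 0)
  list(out = out, cache = X > 0)
}

relu_bwd <- function(dY, cache) dY * cache

# inverted dropout; identity in evaluation mode
dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, cache = NULL))
  mask <- matrix((runif(length(X)) >= p) / (1 - p), nrow(X), ncol(X))
  list(out = X * mask, cache = mask)
}

dropout_bwd <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

pool_indices <- function(B, H, W) {
  H2 <- H %/% 2L
  W2 <- W %/% 2L
  r <- rep(rep(seq_len(H2), times = W2), times = B)
  cc <- rep(rep(seq_len(W2), each = H2), times = B)
  base <- rep((seq_len(B) - 1L) * H * W, each = H2 * W2)
  p11 <- base + (2L * r - 1L) + (2L * cc - 2L) * H
  p12 <- base + (2L * r - 1L) + (2L * cc - 1L) * H
  list(p11, p11 + 1L, p12, p12 + 1L)
}

maxpool_fwd <- function(X, B, H, W) {
  idx <- pool_indices(B, H, W)
  A <- X[idx[[1]], , drop = FALSE]
  B2 <- X[idx[[2]], , drop = FALSE]
  C2 <- X[idx[[3]], , drop = FALSE]
  D2 <- X[idx[[4]], , drop = FALSE]
  M <- pmax(A, B2, C2, D2)
  s1 <- A == M
  s2 <- (B2 == M) & !s1
  s3 <- (C2 == M) & !(s1 | s2)
  s4 <- !(s1 | s2 | s3)
  list(out = M, cache = list(idx = idx, sel = list(s1, s2, s3, s4)))
}

maxpool_bwd <- function(dY, cache, B, H, W, C) {
  dX <- matrix(0, B * H * W, C)
  for (k in 1:4)
    dX[cache$idx[[k]], ] <- dY * cache$sel[[k]]
  dX
}

# 2x2 transposed convolution with stride 2 (the original U-Net up-convolution)
upconv_init <- function(c_in, c_out) {
  list(W = array(rnorm(c_in * c_out * 4L, sd = sqrt(2 / c_in)),
                 dim = c(c_in, c_out, 4L)),
       b = numeric(c_out))
}

up_indices <- function(B, H, W) {
  r <- rep(rep(seq_len(H), times = W), times = B)
  cc <- rep(rep(seq_len(W), each = H), times = B)
  base <- rep((seq_len(B) - 1L) * 4L * H * W, each = H * W)
  H2 <- 2L * H
  f <- function(a, b) base + (2L * r - 1L + a) + (2L * cc - 2L + b) * H2
  list(f(0L, 0L), f(1L, 0L), f(0L, 1L), f(1L, 1L))
}

upconv_fwd <- function(X, par, B, H, W) {
  c_out <- length(par$b)
  idx <- up_indices(B, H, W)
  out <- matrix(0, B * 4L * H * W, c_out)
  for (k in 1:4)
    out[idx[[k]], ] <- X %*% par$W[, , k]
  out <- sweep(out, 2L, par$b, "+")
  list(out = out, cache = list(X = X, idx = idx))
}

upconv_bwd <- function(dY, par, cache, B, H, W) {
  dW <- array(0, dim = dim(par$W))
  dX <- matrix(0, nrow(cache$X), dim(par$W)[1])
  for (k in 1:4) {
    dYk <- dY[cache$idx[[k]], , drop = FALSE]
    dX <- dX + dYk %*% t(par$W[, , k])
    dW[, , k] <- crossprod(cache$X, dYk)
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}
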