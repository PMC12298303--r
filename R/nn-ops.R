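# Low-level differentiable operations for the transformer decomposer.
#
# Activations are 3-D arrays with dim (L, B, d): sequence position, batch
# element, channel. Column-major layout means `dim(X) <- c(L*B, d)` yields a
# matrix whose rows enumerate (position, batch) pairs, so every pointwise
# linear layer is a single BLAS matmul. Each *_fwd returns list(out, cache);
# each *_bwd consumes the upstream gradient plus that cache and returns the
# input gradient and parameter gradients. All of it is exercised by a
# finite-difference gradient check in the test suite.

as_mat <- function(X) {
  d <- dim(X)
  dim(X) <- c(d[1L] * d[2L], d[3L])
  X
}

as_arr <- function(M, L, B) {
  dim(M) <- c(L, B, ncol(M))
  M
}


lin_fwd <- function(X, W, b = NULL) {
  L <- dim(X)[1L]; B <- dim(X)[2L]
  Y <- as_mat(X) %*% W
  if (!is.null(b)) Y <- sweep(Y, 2L, b, "+")
  as_arr(Y, L, B)
}

lin_bwd <- function(dY, X, W, has_bias = FALSE) {
  L <- dim(X)[1L]; B <- dim(X)[2L]
  dYm <- as_mat(dY)
  Xm <- as_mat(X)
  out <- list(dX = as_arr(dYm %*% t(W), L, B), dW = crossprod(Xm, dYm))
  if (has_bias) out$db <- colSums(dYm)
  out
}

# moving average along dim 1 of an (L, m) matrix, replicate padding, and its
# adjoint as a linear operator; thin wrappers over the compiled kernels
ma_cols <- function(M, window) {
  if (window == 1L) return(M)
  storage.mode(M) <- "double"
  ma_cols_cpp(M, as.integer(window))
}

ma_cols_adjoint <- function(G, window) {
  if (window == 1L) return(G)
  storage.mode(G) <- "double"
  ma_cols_adjoint_cpp(G, as.integer(window))
}

# series decomposition sublayer returning both parts: seasonal (detrended)
# continues along the residual stream, trend feeds the decoder's trend
# accumulation path
decomp2_fwd <- function(X, window) {
  L <- dim(X)[1L]; B <- dim(X)[2L]; d <- dim(X)[3L]
  M <- X; dim(M) <- c(L, B * d)
  Tr <- ma_cols(M, window)
  S <- M - Tr
  dim(S) <- c(L, B, d); dim(Tr) <- c(L, B, d)
  list(s = S, t = Tr)
}

# combined backward: dX = dS - MA^T(dS) + MA^T(dT)
decomp2_bwd <- function(dS, dT, window) {
  L <- dim(dS)[1L]; B <- dim(dS)[2L]; d <- dim(dS)[3L]
  G <- dS; dim(G) <- c(L, B * d)
  GX <- G - ma_cols_adjoint(G, window)
  if (!is.null(dT)) {
    GT <- dT; dim(GT) <- c(L, B * d)
    GX <- GX + ma_cols_adjoint(GT, window)
  }
  dim(GX) <- c(L, B, d)
  GX
}

# series decomposition sublayer: keep the seasonal (detrended) part
decomp_fwd <- function(X, window) {
  L <- dim(X)[1L]; B <- dim(X)[2L]; d <- dim(X)[3L]
  M <- X; dim(M) <- c(L, B * d)
  S <- M - ma_cols(M, window)
  dim(S) <- c(L, B, d)
  S
}

decomp_bwd <- function(dS, window) {
  L <- dim(dS)[1L]; B <- dim(dS)[2L]; d <- dim(dS)[3L]
  G <- dS; dim(G) <- c(L, B * d)
  GX <- G - ma_cols_adjoint(G, window)
  dim(GX) <- c(L, B, d)
  GX
}

# value embedding: kernel-3 convolution of the scalar series into d channels,
# replicate padding, no bias
embed_fwd <- function(x, W) {
  # x: B x L matrix of raw series; W: 3 x d
  B <- nrow(x); L <- ncol(x)
  Xn <- array(0, c(L, B, 3L))
  tx <- t(x)                       # L x B
  Xn[, , 1L] <- tx[c(1L, seq_len(L - 1L)), , drop = FALSE]
  Xn[, , 2L] <- tx
  Xn[, , 3L] <- tx[c(seq(2L, length.out = L - 1L), L), , drop = FALSE]
  list(out = lin_fwd(Xn, W), cache = Xn)
}

embed_bwd <- function(dY, cache, W) {
  L <- dim(dY)[1L]; B <- dim(dY)[2L]
  lb <- lin_bwd(dY, cache, W)
  dXn <- lb$dX
  dx <- matrix(0, L, B)
  dm1 <- dXn[, , 1L, drop = FALSE]; dim(dm1) <- c(L, B)
  d0  <- dXn[, , 2L, drop = FALSE]; dim(d0) <- c(L, B)
  dp1 <- dXn[, , 3L, drop = FALSE]; dim(dp1) <- c(L, B)
  dx <- d0
  dx[seq_len(L - 1L), ] <- dx[seq_len(L - 1L), , drop = FALSE] +
    dm1[seq(2L, L), , drop = FALSE]
  dx[1L, ] <- dx[1L, ] + dm1[1L, ]
  dx[seq(2L, L), ] <- dx[seq(2L, L), , drop = FALSE] +
    dp1[seq_len(L - 1L), , drop = FALSE]
  dx[L, ] <- dx[L, ] + dp1[L, ]
  list(dx = t(dx), dW = lb$dW)      # dx back as B x L
}

relu_fwd <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}

# layer normalization over the channel dimension with learned gain/bias
ln_fwd <- function(X, g, b, eps = 1e-5) {
  L <- dim(X)[1L]; B <- dim(X)[2L]; d <- dim(X)[3L]
  M <- as_mat(X)
  mu <- rowMeans(M)
  xc <- M - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- sweep(xhat, 2L, g, "*")
  Y <- sweep(Y, 2L, b, "+")
  list(out = as_arr(Y, L, B), cache = list(xhat = xhat, inv = inv))
}

ln_bwd <- function(dY, cache, g) {
  L <- dim(dY)[1L]; B <- dim(dY)[2L]; d <- dim(dY)[3L]
  dYm <- as_mat(dY)
  xhat <- cache$xhat
  dg <- colSums(dYm * xhat)
  db <- colSums(dYm)
  dxhat <- sweep(dYm, 2L, g, "*")
  # standard layernorm backward over the normalized axis
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dX = as_arr(dX, L, B), dg = dg, db = db)
}

# autocorrelation attention: delays scored by the channel-averaged circular
# cross-correlation of queries and keys (computed by FFT), top-k delays kept,
# softmax-weighted aggregation of time-rolled values
autocorr_fwd <- function(Xq, Xkv, p, top_k) {
  L <- dim(Xq)[1L]; B <- dim(Xq)[2L]
  Q <- lin_fwd(Xq, p$Wq)
  K <- lin_fwd(Xkv, p$Wk)
  V <- lin_fwd(Xkv, p$Wv)
  d <- dim(Q)[3L]
  FQ <- Q; dim(FQ) <- c(L, B * d); FQ <- stats::mvfft(FQ)
  FK <- K; dim(FK) <- c(L, B * d); FK <- stats::mvfft(FK)
  S <- Conj(FQ) * FK
  dim(S) <- c(L * B, d)
  Ssum <- rowSums(S)                           # collapse channels
  dim(Ssum) <- c(L, B)
  corr <- Re(stats::mvfft(Ssum, inverse = TRUE)) / (L * L * d)
  idx <- matrix(0L, top_k, B)                  # delay tau = idx - 1
  wts <- matrix(0, top_k, B)
  for (b in seq_len(B)) {
    ord <- order(corr[, b], decreasing = TRUE)[seq_len(top_k)]
    idx[, b] <- ord
    a <- corr[ord, b]
    w <- exp(a - max(a))
    wts[, b] <- w / sum(w)
  }
  Out <- agg_fwd_cpp(V, idx, wts)
  Y <- lin_fwd(Out, p$Wo)
  list(out = Y,
       cache = list(Q = Q, K = K, V = V, Out = Out, idx = idx, wts = wts,
                    Xq = Xq, Xkv = Xkv))
}

autocorr_bwd <- function(dY, cache, p) {
  Q <- cache$Q; K <- cache$K; V <- cache$V
  L <- dim(Q)[1L]; B <- dim(Q)[2L]; d <- dim(Q)[3L]
  top_k <- nrow(cache$idx)
  lo <- lin_bwd(dY, cache$Out, p$Wo)
  dOut <- lo$dX
  ag <- agg_bwd_cpp(Q, K, V, dOut, cache$idx, cache$wts, 1 / (L * d))
  bq <- lin_bwd(ag$dQ, cache$Xq, p$Wq)
  bk <- lin_bwd(ag$dK, cache$Xkv, p$Wk)
  bv <- lin_bwd(ag$dV, cache$Xkv, p$Wv)
  list(dXq = bq$dX, dXkv = bk$dX + bv$dX,
       grads = list(Wq = bq$dW, Wk = bk$dW, Wv = bv$dW, Wo = lo$dW))
}

# position-wise feed-forward block: conv1x1 d -> ff, ReLU, conv1x1 ff -> d
ff_fwd <- function(X, p) {
  H <- lin_fwd(X, p$W1, p$b1)
  r <- relu_fwd(H)
  Y <- lin_fwd(r$out, p$W2, p$b2)
  list(out = Y, cache = list(X = X, Hr = r$out, mask = r$cache))
}

ff_bwd <- function(dY, cache, p) {
  l2 <- lin_bwd(dY, cache$Hr, p$W2, has_bias = TRUE)
  dH <- l2$dX * cache$mask
  l1 <- lin_bwd(dH, cache$X, p$W1, has_bias = TRUE)
  list(dX = l1$dX,
       grads = list(W1 = l1$dW, b1 = l1$db, W2 = l2$dW, b2 = l2$db))
}
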