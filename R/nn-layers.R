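# 1D convolutional network primitives. Batches are stored channel-major:
# an array of dim (C, L, N). Convolutions are computed as im2col gathers
# followed by a single BLAS matrix multiply; backward scatters gradients
# with rowsum() over the same gather index. All layers return explicit
# caches so the network backward pass is exact (verified against finite
# differences in the test suite).

conv_out_len <- function(L, k, stride, pad) (L + 2L * pad - k) %/% stride + 1L

# Gather index for im2col on a (C, L_pad) column-major slab. Row order of
# the resulting (k*C, L_out*N) matrix: channel fastest within tap.
make_im2col_index <- function(C, L, k, stride, pad) {
  L_out <- conv_out_len(L, k, stride, pad)
  starts <- (seq_len(L_out) - 1L) * stride          # 0-based into padded
  taps <- rep(seq_len(k), each = C)                  # 1..k
  chans <- rep(seq_len(C), times = k)
  idx <- integer(k * C * L_out)
  blk <- k * C
  for (l in seq_len(L_out)) {
    p <- starts[l] + taps                            # 1-based padded pos
    idx[((l - 1L) * blk + 1L):(l * blk)] <- (p - 1L) * C + chans
  }
  list(idx = idx, L_out = L_out, L_pad = L + 2L * pad)
}

conv1d_forward <- function(X, W, meta) {
  # X: (C, L, N); W: (C_out, k*C)
  d <- dim(X); C <- d[1]; L <- d[2]; N <- d[3]
  Xmat <- X; dim(Xmat) <- c(C * L, N)
  if (meta$pad > 0L) {
    Xp <- matrix(0, C * meta$im$L_pad, N)
    Xp[(meta$pad * C + 1L):((meta$pad + L) * C), ] <- Xmat
  } else Xp <- Xmat
  M <- Xp[meta$im$idx, , drop = FALSE]
  dim(M) <- c(meta$k * C, meta$im$L_out * N)
  Y <- W %*% M
  dim(Y) <- c(nrow(W), meta$im$L_out, N)
  list(out = Y, cache = list(M = M, dimX = d))
}

conv1d_backward <- function(dY, W, meta, cache) {
  d <- cache$dimX; C <- d[1]; L <- d[2]; N <- d[3]
  C_out <- nrow(W)
  dim(dY) <- c(C_out, meta$im$L_out * N)
  dW <- dY %*% t(cache$M)
  dM <- crossprod(W, dY)                             # (k*C, L_out*N)
  dim(dM) <- c(meta$k * C * meta$im$L_out, N)
  acc <- rowsum(dM, group = meta$im$idx)             # unique idx sorted
  dXp <- matrix(0, C * meta$im$L_pad, N)
  dXp[as.integer(rownames(acc)), ] <- acc
  dX <- dXp[(meta$pad * C + 1L):((meta$pad + L) * C), , drop = FALSE]
  dim(dX) <- d
  list(dX = dX, dW = dW)
}

bn_forward <- function(X, gamma, beta, state, training, momentum = 0.1,
                       eps = 1e-5) {
  d <- dim(X); C <- d[1]
  Xm <- X; dim(Xm) <- c(C, d[2] * d[3])
  if (training) {
    mu <- rowMeans(Xm)
    v <- rowMeans(Xm^2) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    m <- ncol(Xm)
    state$var <- (1 - momentum) * state$var +
      momentum * v * m / max(1, m - 1)
  } else {
    mu <- state$mean; v <- state$var
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- (Xm - mu) * inv_std
  Y <- gamma * xhat + beta
  dim(Y) <- d
  list(out = Y, state = state,
       cache = list(xhat = xhat, inv_std = inv_std, dimX = d))
}

bn_backward <- function(dY, gamma, cache) {
  d <- cache$dimX; C <- d[1]; m <- d[2] * d[3]
  dYm <- dY; dim(dYm) <- c(C, m)
  xhat <- cache$xhat
  dgamma <- rowSums(dYm * xhat)
  dbeta <- rowSums(dYm)
  dxhat <- dYm * gamma
  dX <- cache$inv_std * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}
relu_backward <- function(dY, mask) dY * mask

gap_forward <- function(X) {
  d <- dim(X); C <- d[1]; L <- d[2]; N <- d[3]
  Xm <- X; dim(Xm) <- c(C * L, N)
  feat <- rowsum(Xm, group = rep(seq_len(C), times = L)) / L
  list(out = feat, cache = d)                        # feat: (C, N)
}
gap_backward <- function(dfeat, d) {
  C <- d[1]; L <- d[2]
  dX <- dfeat[rep(seq_len(C), times = L), , drop = FALSE] / L
  dim(dX) <- d
  dX
}

linear_forward <- function(X, W, b) {
  list(out = W %*% X + b, cache = X)                 # X: (C_in, N)
}
linear_backward <- function(dY, W, cache) {
  list(dX = crossprod(W, dY), dW = dY %*% t(cache), db = rowSums(dY))
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

# Cross-entropy over column-wise logits; y: integer class ids (1-based),
# w: optional per-class weights.
cross_entropy <- function(logits, y, w = NULL) {
  P <- softmax_cols(logits)
  N <- ncol(P)
  k <- nrow(P)
  pick <- cbind(y, seq_len(N))                       # row=class, col=sample
  if (is.null(w)) w <- rep(1, k)
  wi <- w[y]
  loss <- -sum(wi * log(pmax(t(P)[cbind(seq_len(N), y)], 1e-12))) / sum(wi)
  G <- P
  G[cbind(y, seq_len(N))] <- G[cbind(y, seq_len(N))] - 1
  G <- sweep(G, 2, wi, "*") / sum(wi)
  list(loss = loss, grad = G, probs = P)
}
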