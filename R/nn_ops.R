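# Internal neural-network primitives. Signals are arrays [channels, time,
# batch]; a 1-D convolution with odd kernel K and 'same' zero padding is
# computed as K shifted matrix products, which keeps everything in BLAS.
# Backward passes are exact gradients (checked against finite differences in
# the test suite).

# ---- convolution ----------------------------------------------------------

.conv1d_fwd <- function(X, W, b, stride = 1L) {
  dX <- dim(X)
  C <- dX[1]; Tt <- dX[2]; B <- dX[3]
  Cout <- dim(W)[1]; K <- dim(W)[3]
  pad <- (K - 1L) %/% 2L
  Xm <- matrix(X, C, Tt * B)
  Ym <- matrix(0, Cout, Tt * B)
  block <- (seq_len(B) - 1L) * Tt
  for (j in seq_len(K)) {
    off <- j - 1L - pad
    t_dst <- seq_len(Tt)
    t_src <- t_dst + off
    keep <- t_src >= 1L & t_src <= Tt
    if (!any(keep)) next
    dst <- as.vector(outer(t_dst[keep], block, "+"))
    src <- as.vector(outer(t_src[keep], block, "+"))
    Ym[, dst] <- Ym[, dst] + matrix(W[, , j], Cout, C) %*% Xm[, src, drop = FALSE]
  }
  Ym <- Ym + b
  if (stride > 1L) {
    t_keep <- seq.int(1L, Tt, by = stride)
    cols <- as.vector(outer(t_keep, block, "+"))
    Ym <- Ym[, cols, drop = FALSE]
    Tt <- length(t_keep)
  }
  array(Ym, dim = c(Cout, Tt, B))
}

.conv1d_bwd <- function(X, W, dY, stride = 1L) {
  dXd <- dim(X)
  C <- dXd[1]; Tt <- dXd[2]; B <- dXd[3]
  Cout <- dim(W)[1]; K <- dim(W)[3]
  pad <- (K - 1L) %/% 2L
  block <- (seq_len(B) - 1L) * Tt
  # scatter strided dY back onto the full time grid
  if (stride > 1L) {
    t_keep <- seq.int(1L, Tt, by = stride)
    full <- matrix(0, Cout, Tt * B)
    cols <- as.vector(outer(t_keep, block, "+"))
    full[, cols] <- matrix(dY, Cout, length(t_keep) * B)
    dYm <- full
  } else {
    dYm <- matrix(dY, Cout, Tt * B)
  }
  Xm <- matrix(X, C, Tt * B)
  dXm <- matrix(0, C, Tt * B)
  dW <- array(0, dim = dim(W))
  for (j in seq_len(K)) {
    off <- j - 1L - pad
    t_dst <- seq_len(Tt)
    t_src <- t_dst + off
    keep <- t_src >= 1L & t_src <= Tt
    if (!any(keep)) next
    dst <- as.vector(outer(t_dst[keep], block, "+"))
    src <- as.vector(outer(t_src[keep], block, "+"))
    dW[, , j] <- dYm[, dst, drop = FALSE] %*% t(Xm[, src, drop = FALSE])
    dXm[, src] <- dXm[, src] + t(matrix(W[, , j], Cout, C)) %*% dYm[, dst, drop = FALSE]
  }
  list(dX = array(dXm, dim = c(C, Tt, B)),
       dW = dW,
       db = rowSums(dYm))
}

# ---- batch normalization --------------------------------------------------

.bn_fwd <- function(X, p, training = TRUE, momentum = 0.1, eps = 1e-5) {
  d <- dim(X)
  Xm <- matrix(X, d[1], d[2] * d[3])
  if (training) {
    mu <- rowMeans(Xm)
    v <- rowMeans((Xm - mu)^2)
    p$rmean <- (1 - momentum) * p$rmean + momentum * mu
    p$rvar <- (1 - momentum) * p$rvar + momentum * v
  } else {
    mu <- p$rmean
    v <- p$rvar
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- (Xm - mu) * ivar
  Y <- array(p$gamma * xhat + p$beta, dim = d)
  list(Y = Y, p = p, cache = list(xhat = xhat, ivar = ivar, dim = d))
}

.bn_bwd <- function(dY, p, cache) {
  d <- cache$dim
  m <- d[2] * d[3]
  dYm <- matrix(dY, d[1], m)
  xhat <- cache$xhat
  dgamma <- rowSums(dYm * xhat)
  dbeta <- rowSums(dYm)
  dxhat <- dYm * p$gamma
  dXm <- (cache$ivar / m) * (m * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  list(dX = array(dXm, dim = d), dgamma = dgamma, dbeta = dbeta)
}

# ---- activations / pooling / dense ---------------------------------------

.relu <- function(X) {
  X[X < 0] <- 0
  X
}

.relu_bwd <- function(dY, Y) {
  dY[Y <= 0] <- 0
  dY
}

# global average pooling over time: [C,T,B] -> [C,B]
.gap_fwd <- function(X) {
  d <- dim(X)
  m <- matrix(X, d[1], d[2] * d[3])
  out <- matrix(0, d[1], d[3])
  for (b in seq_len(d[3])) {
    out[, b] <- rowMeans(m[, (b - 1L) * d[2] + seq_len(d[2]), drop = FALSE])
  }
  out
}

.gap_bwd <- function(dOut, Tt) {
  C <- nrow(dOut); B <- ncol(dOut)
  dX <- array(0, dim = c(C, Tt, B))
  for (b in seq_len(B)) dX[, , b] <- matrix(dOut[, b] / Tt, C, Tt)
  dX
}

.softmax_cols <- function(Z) {
  Z <- Z - matrix(apply(Z, 2, max), nrow(Z), ncol(Z), byrow = TRUE)
  E <- exp(Z)
  E / matrix(colSums(E), nrow(Z), ncol(Z), byrow = TRUE)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- parameter-tree optimizer steps ---------------------------------------
# Parameters, gradients, and optimizer state are parallel nested lists of
# numeric arrays; these walkers update them in lockstep.

.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) {
      if (!is.null(a[[nm]])) out[[nm]] <- .tree_map2(f, a[[nm]], b[[nm]])
    }
    out
  } else {
    f(a, b)
  }
}

.tree_zeros <- function(a) {
  if (is.list(a)) {
    lapply(a, function(e) if (is.null(e)) NULL else .tree_zeros(e))
  } else {
    a * 0
  }
}

.sgd_step <- function(params, grads, vel, lr, momentum = 0.9) {
  vel <- .tree_map2(function(v, g) momentum * v + g, vel, grads)
  params <- .tree_map2(function(p, v) p - lr * v, params, vel)
  list(params = params, vel = vel)
}

.adam_step <- function(params, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  mh <- .tree_map2(function(m, g) m / (1 - beta1^t), state$m, state$m)
  vh <- .tree_map2(function(v, g) v / (1 - beta2^t), state$v, state$v)
  step <- .tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mh, vh)
  params <- .tree_map2(function(p, s) p - s, params, step)
  list(params = params, state = state)
}

.he_init <- function(cout, cin, k = NULL) {
  if (is.null(k)) {
    matrix(rnorm(cout * cin, sd = sqrt(2 / cin)), cout, cin)
  } else {
    array(rnorm(cout * cin * k, sd = sqrt(2 / (cin * k))), dim = c(cout, cin, k))
  }
}
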