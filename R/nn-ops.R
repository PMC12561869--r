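# Neural-network layers with hand-derived backward passes. The dense loops
# (im2col convolution, fused batch-norm + LeakyReLU, max pooling, LSTM
# recursion, channel broadcasts) live in src/kernels.cpp; this file holds
# the layer contracts, caching and the remaining matrix algebra.
# Activations flow as (features, time, batch) arrays or (features, batch)
# matrices, so per-feature reductions recycle column-wise without copies.

.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- convolution -----------------------------------------------------------

# x: (Cin, L, B); W: (F, Cin*kernel); b: length F.
# Returns out (F, Lout, B) and, when caching, the im2col matrix for the
# weight gradient.
convForward <- function(x, W, b, kernel, stride, keepCache = TRUE) {
  if (dim(x)[2] < kernel) {
    stopf("input length %d shorter than kernel %d", dim(x)[2], kernel)
  }
  cpp_conv_fwd(x, W, b, kernel, stride, keepCache)
}

# Gradients of weights/bias only: convolution is always the first layer, so
# no input gradient is required.
convBackward <- function(dout, xc) cpp_conv_bwd(dout, xc)

# ---- fused batch normalization + LeakyReLU --------------------------------

# x: (F, N) where N pools time and batch; per-feature statistics with biased
# variance. Training mode returns updated running statistics; evaluation
# mode uses them. LeakyReLU keeps the sign of its input, so the backward
# mask is the sign of the forward output and needs no extra cache.
bnLeakyForward <- function(x, g, b, rm, rv, training, slope,
                           momentum = 0.1, eps = 1e-5) {
  cpp_bn_leaky_fwd(x, g, b, rm, rv, training, momentum, eps, slope)
}

bnLeakyBackward <- function(dout, out, g, xhat, invstd, slope) {
  cpp_bn_leaky_bwd(dout, out, g, xhat, invstd, slope)
}

# ---- pooling / dropout -----------------------------------------------------

# x: (F, L, B); non-overlapping windows of size pool, floor division.
maxpoolForward <- function(x, pool) {
  mp <- cpp_maxpool_fwd(x, pool)
  mp$pool <- pool
  mp$lin <- dim(x)[2]
  mp
}

maxpoolBackward <- function(dout, cache) {
  cpp_maxpool_bwd(dout, cache$arg, cache$pool, cache$lin)
}

# Inverted dropout; draws from the R RNG so fixed seeds reproduce runs.
dropoutForward <- function(x, p, training) {
  if (!training || p <= 0) {
    return(list(out = x, mask = NULL))
  }
  mask <- array((stats::runif(length(x)) >= p) / (1 - p), dim = dim(x))
  list(out = x * mask, mask = mask)
}

dropoutBackward <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

# ---- squeeze-and-excitation ------------------------------------------------

# x: (F, T, B). Squeeze: per-channel global average over time. Excite: two
# fully connected layers (ReLU then sigmoid, no biases). Scale: per-channel
# multiplicative gate in (0, 1).
seForward <- function(x, W1, W2) {
  z <- cpp_time_mean(x)
  a <- W1 %*% z
  a[a < 0] <- 0
  s <- .sigmoid(W2 %*% a)
  list(out = cpp_scale_channels(x, s), z = z, a = a, s = s)
}

seBackward <- function(dout, x, W1, W2, cache) {
  Tn <- dim(x)[2]
  ds <- cpp_time_mean(dout * x) * Tn
  dx <- cpp_scale_channels(dout, cache$s)
  dpre2 <- ds * cache$s * (1 - cache$s)
  dW2 <- dpre2 %*% t(cache$a)
  da <- crossprod(W2, dpre2)
  da[cache$a <= 0] <- 0
  dW1 <- da %*% t(cache$z)
  dz <- crossprod(W1, da) / Tn
  list(dx = cpp_add_channels(dx, dz), dW1 = dW1, dW2 = dW2)
}

# ---- LSTM ------------------------------------------------------------------

# One direction over x (D, T, B); gate order i, f, g, o stacked in rows.
lstmDirForward <- function(x, Wx, Wh, b, reverse = FALSE) {
  fw <- cpp_lstm_fwd(x, Wx, Wh, b, reverse)
  fw$reverse <- reverse
  fw$x <- x
  fw
}

# dhs: (H, T, B) gradient into each h_t from layers above.
lstmDirBackward <- function(dhs, Wx, Wh, cache) {
  cpp_lstm_bwd(
    dhs, cache$x, cache$hs, cache$I, cache$Fg, cache$G, cache$O,
    cache$C, cache$TC, Wx, Wh, cache$reverse
  )
}

# ---- attention pooling -----------------------------------------------------

# hs: (Dh, T, B). Scores e_t = v' tanh(Wh h_t + bh); alpha = softmax over t;
# context c = sum_t alpha_t h_t.
attnForward <- function(hs, Wh, bh, v) {
  d <- dim(hs)
  Tn <- d[2]
  B <- d[3]
  U <- array(0, c(length(bh), Tn, B))
  E <- matrix(0, Tn, B)
  for (t in seq_len(Tn)) {
    u <- tanh(Wh %*% matrix(hs[, t, ], d[1], B) + bh)
    U[, t, ] <- u
    E[t, ] <- crossprod(u, v)
  }
  E <- exp(E - matrix(apply(E, 2, max), Tn, B, byrow = TRUE))
  alpha <- E / matrix(colSums(E), Tn, B, byrow = TRUE)
  ctx <- matrix(0, d[1], B)
  for (t in seq_len(Tn)) {
    ht <- matrix(hs[, t, ], d[1], B)
    ctx <- ctx + t(t(ht) * alpha[t, ])
  }
  list(ctx = ctx, alpha = alpha, U = U)
}

attnBackward <- function(dctx, hs, Wh, v, cache) {
  d <- dim(hs)
  Tn <- d[2]
  B <- d[3]
  alpha <- cache$alpha
  dalpha <- matrix(0, Tn, B)
  dhs <- array(0, d)
  for (t in seq_len(Tn)) {
    ht <- matrix(hs[, t, ], d[1], B)
    dalpha[t, ] <- colSums(dctx * ht)
    dhs[, t, ] <- t(t(dctx) * alpha[t, ])
  }
  S <- colSums(dalpha * alpha)
  dE <- alpha * (dalpha - matrix(S, Tn, B, byrow = TRUE))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  dbh <- numeric(dim(cache$U)[1])
  dv <- numeric(length(v))
  for (t in seq_len(Tn)) {
    u <- matrix(cache$U[, t, ], nrow(Wh), B)
    du <- outer(v, dE[t, ])
    dv <- dv + as.vector(u %*% dE[t, ])
    dpre <- du * (1 - u * u)
    dWh <- dWh + dpre %*% t(matrix(hs[, t, ], d[1], B))
    dbh <- dbh + rowSums(dpre)
    dhs[, t, ] <- dhs[, t, ] + crossprod(Wh, dpre)
  }
  list(dhs = dhs, dWh = dWh, dbh = dbh, dv = dv)
}

# ---- softmax / cross-entropy ----------------------------------------------

softmaxCols <- function(logits) {
  e <- exp(logits - matrix(apply(logits, 2, max), nrow(logits), ncol(logits),
    byrow = TRUE
  ))
  e / matrix(colSums(e), nrow(logits), ncol(logits), byrow = TRUE)
}

# logits: (K, B); labels: integer 0..K-1. Loss computed from logits via
# log-sum-exp (never from normalized probabilities), optionally with
# per-class weights on the true class. Returns mean loss and dlogits.
xentFromLogits <- function(logits, labels, classWeights = NULL) {
  K <- nrow(logits)
  B <- ncol(logits)
  mx <- apply(logits, 2, max)
  lse <- mx + log(colSums(exp(logits - matrix(mx, K, B, byrow = TRUE))))
  sel <- cbind(labels + 1L, seq_len(B))
  ce <- lse - logits[sel]
  w <- if (is.null(classWeights)) rep(1, B) else classWeights[labels + 1L]
  loss <- mean(w * ce)
  p <- softmaxCols(logits)
  y <- matrix(0, K, B)
  y[sel] <- 1
  dlogits <- (p - y) * matrix(w, K, B, byrow = TRUE) / B
  list(loss = loss, dlogits = dlogits, probs = p)
}

# ---- initialization --------------------------------------------------------

initUniform <- function(nr, nc, fanIn) {
  s <- 1 / sqrt(fanIn)
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

initUniformVec <- function(n, fanIn) {
  s <- 1 / sqrt(fanIn)
  stats::runif(n, -s, s)
}
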