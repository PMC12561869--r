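test_that("convolution output lengths follow the conv arithmetic", {
  # small branch: (3000 - 50) / 6 + 1 = 492 -> /8 -> 61
  expect_equal(sleepnet:::convOutLen(3000, 50, 6, 8), 61)
  # large branch: (3000 - 400) / 50 + 1 = 53 -> /4 -> 13
  expect_equal(sleepnet:::convOutLen(3000, 400, 50, 4), 13)
  # directly through the layer
  x <- array(stats::rnorm(2 * 3000 * 3), c(2, 3000, 3))
  W <- matrix(stats::rnorm(64 * 100, sd = .1), 64, 100)
  cv <- sleepnet:::convForward(x, W, numeric(64), 50, 6)
  expect_equal(dim(cv$out), c(64, 492, 3))
  expect_error(
    sleepnet:::convForward(array(0, c(1, 30, 1)), W, numeric(64), 50, 6),
    "shorter than kernel"
  )
})

test_that("default forward pass meets the shape contract", {
  m <- memoFixture("fullModel", function() buildVariant("full", seed = 42))
  set.seed(1)
  x <- array(stats::rnorm(2 * 4 * 3000), c(2, 4, 3000))
  feats <- mfemForward(m, x)
  expect_equal(dim(feats), c(2, 74, 192))
  fw <- sleepnet:::sleepNetForward(m, x)
  expect_equal(dim(fw$logits), c(5, 2))
  probs <- predictStages(m, x, returnProbs = TRUE)$probs
  expect_equal(dim(probs), c(2, 5))
  expect_equal(rowSums(probs), c(1, 1), tolerance = 1e-6)
  # attention weights sum to 1 per sample
  expect_equal(colSums(fw$alpha), c(1, 1), tolerance = 1e-12)
  expect_error(
    sleepnet:::sleepNetForward(m, array(0, c(2, 2, 3000))),
    "4 input channels"
  )
})

test_that("evaluation-mode forward passes are deterministic", {
  m <- memoFixture("fullModel", function() buildVariant("full", seed = 42))
  set.seed(2)
  x <- array(stats::rnorm(3 * 4 * 3000), c(3, 4, 3000))
  p1 <- predictStages(m, x, returnProbs = TRUE)$probs
  p2 <- predictStages(m, x, returnProbs = TRUE)$probs
  expect_identical(p1, p2)
})

test_that("squeeze-and-excitation follows its defining algebra", {
  set.seed(3)
  Fn <- 8
  Tn <- 6
  B <- 4
  x <- array(stats::rnorm(Fn * Tn * B), c(Fn, Tn, B))
  W1 <- matrix(stats::rnorm(2 * Fn), 2, Fn)
  W2 <- matrix(stats::rnorm(Fn * 2), Fn, 2)
  got <- seLayer(x, W1, W2)
  # brute-force elementwise oracle
  for (b in 1:B) {
    z <- sapply(1:Fn, function(f) mean(x[f, , b]))
    s <- 1 / (1 + exp(-(W2 %*% pmax(W1 %*% z, 0))))
    for (f in 1:Fn) {
      expect_equal(got$out[f, , b], x[f, , b] * s[f], tolerance = 1e-6)
    }
    expect_true(all(got$gates[, b] > 0 & got$gates[, b] < 1))
  }
  # zero weights: sigmoid(0) = 0.5 exactly
  z0 <- seLayer(x, W1 * 0, W2 * 0)
  expect_equal(z0$out, 0.5 * x, tolerance = 0)
  # squeeze is linear: doubling the input doubles the pooled statistic
  expect_equal(sleepnet:::cpp_time_mean(2 * x), 2 * sleepnet:::cpp_time_mean(x))
})

test_that("zeroing the SE weights halves the modality features", {
  cfg <- tinyConfig()
  mFull <- buildVariant("full", cfg, seed = 5)
  for (nm in grep("\\.se\\.", names(mFull@params), value = TRUE)) {
    mFull@params[[nm]][] <- 0
  }
  mNoSe <- buildVariant("no_se", cfg, seed = 5)
  # share the non-SE parameters so the two paths differ only in the gate
  for (nm in names(mNoSe@params)) mNoSe@params[[nm]] <- mFull@params[[nm]]
  set.seed(6)
  x <- array(stats::rnorm(2 * 4 * 300), c(2, 4, 300))
  expect_equal(mfemForward(mFull, x), 0.5 * mfemForward(mNoSe, x),
    tolerance = 1e-12
  )
})

test_that("attention pooling matches a brute-force softmax oracle", {
  set.seed(7)
  Dh <- 6
  Tn <- 9
  B <- 3
  A <- 4
  hs <- array(stats::rnorm(Dh * Tn * B), c(Dh, Tn, B))
  Wh <- matrix(stats::rnorm(A * Dh), A, Dh)
  bh <- stats::rnorm(A)
  v <- stats::rnorm(A)
  got <- attentionPool(hs, Wh, bh, v)
  for (b in 1:B) {
    e <- sapply(1:Tn, function(t) sum(v * tanh(Wh %*% hs[, t, b] + bh)))
    alpha <- exp(e) / sum(exp(e))
    expect_equal(got$alpha[, b], alpha, tolerance = 1e-6)
    expect_equal(got$context[, b],
      as.vector(hs[, , b] %*% alpha),
      tolerance = 1e-6
    )
    expect_equal(sum(got$alpha[, b]), 1, tolerance = 1e-12)
  }
  # single time step: softmax over one element
  one <- attentionPool(hs[, 1, , drop = FALSE], Wh, bh, v)
  expect_equal(as.vector(one$alpha), rep(1, B))
  expect_equal(one$context, matrix(hs[, 1, ], Dh, B), tolerance = 1e-12)
  # equal states: the convex combination is that state, whatever the weights
  same <- array(rep(hs[, 1, ], Tn), c(Dh, B, Tn))
  same <- aperm(same, c(1, 3, 2))
  eq <- attentionPool(same, Wh, bh, v)
  expect_equal(eq$context, matrix(hs[, 1, ], Dh, B), tolerance = 1e-9)
})

test_that("classifier head has the softmax identities", {
  ctx <- matrix(stats::rnorm(12), 6, 2)
  W0 <- matrix(0, 5, 6)
  p <- classifyContext(ctx, W0, numeric(5))
  expect_equal(as.vector(p), rep(0.2, 10), tolerance = 1e-12)
  set.seed(8)
  W <- matrix(stats::rnorm(30), 5, 6)
  b <- stats::rnorm(5)
  p1 <- classifyContext(ctx, W, b)
  p2 <- classifyContext(ctx, W, b + 3.7) # constant logit shift
  expect_equal(p1, p2, tolerance = 1e-6)
  logits <- W %*% ctx + b
  expect_equal(max.col(t(p1)), max.col(t(logits)))
  expect_equal(colSums(p1), c(1, 1), tolerance = 1e-12)
})

test_that("cross-entropy equals its definition and handles extremes", {
  # uniform prediction: -log(1/5)
  logits <- matrix(0, 5, 3)
  expect_equal(crossEntropyLoss(logits, c(0L, 2L, 4L)), log(5),
    tolerance = 1e-12
  )
  # perfect one-hot prediction: loss 0
  hot <- matrix(-1e4, 5, 2)
  hot[cbind(c(1, 3), 1:2)] <- 1e4
  expect_equal(crossEntropyLoss(hot, c(0L, 2L)), 0, tolerance = 1e-9)
  # brute-force oracle on random logits
  set.seed(9)
  logits <- matrix(stats::rnorm(5 * 8, sd = 3), 5, 8)
  y <- sample(0:4, 8, replace = TRUE)
  probs <- apply(logits, 2, function(z) exp(z) / sum(exp(z)))
  want <- mean(-log(probs[cbind(y + 1, 1:8)]))
  expect_equal(crossEntropyLoss(logits, y), want, tolerance = 1e-6)
  # weighted: each term scaled by its true-class weight
  w <- c(2, 1, 1, 1, 0.5)
  wantW <- mean(w[y + 1] * -log(probs[cbind(y + 1, 1:8)]))
  expect_equal(crossEntropyLoss(logits, y, w), wantW, tolerance = 1e-6)
})

test_that("the EEG derivations are not interchangeable", {
  m <- buildVariant("full", tinyConfig(), seed = 10)
  set.seed(11)
  x <- array(stats::rnorm(1 * 4 * 300), c(1, 4, 300))
  xswap <- x
  xswap[, 1:2, ] <- x[, 2:1, ]
  f1 <- mfemForward(m, x)
  f2 <- mfemForward(m, xswap)
  expect_gt(max(abs(f1 - f2)), 1e-6)
})

test_that("all six variants honor the interface contract", {
  cfg <- tinyConfig()
  set.seed(12)
  x4 <- array(stats::rnorm(2 * 4 * 300), c(2, 4, 300))
  nPar <- numeric(0)
  for (v in c("full", "no_msconv", "eeg_only", "no_se", "no_lstm", "no_attn")) {
    m <- buildVariant(v, cfg, seed = 13)
    p <- predictStages(m, x4, returnProbs = TRUE)$probs
    expect_equal(dim(p), c(2, 5))
    expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
    nPar[v] <- nParameters(m)
  }
  expect_lt(nPar["eeg_only"], nPar["full"])
  expect_lt(nPar["no_se"], nPar["full"])
  expect_lt(nPar["no_lstm"], nPar["full"])
  # no_attn shares every parameter shape with full except the attention
  mF <- buildVariant("full", cfg, seed = 13)
  mA <- buildVariant("no_attn", cfg, seed = 13)
  expect_setequal(
    setdiff(names(mF@params), names(mA@params)),
    c("attn.Wh", "attn.bh", "attn.v")
  )
  shared <- intersect(names(mF@params), names(mA@params))
  for (nm in shared) {
    expect_identical(dim(mF@params[[nm]]), dim(mA@params[[nm]]))
  }
  expect_error(buildVariant("bogus", cfg), "no_msconv")
})

test_that("reduced time axis of the single-branch variant", {
  cfg <- tinyConfig()
  m <- buildVariant("no_msconv", cfg, seed = 14)
  set.seed(15)
  x <- array(stats::rnorm(2 * 4 * 300), c(2, 4, 300))
  lSmall <- sleepnet:::convOutLen(300, cfg$smallKernel, cfg$smallStride,
    cfg$smallPool)
  expect_equal(dim(mfemForward(m, x))[2], lSmall)
})

test_that("one optimizer step decreases the batch loss for every variant", {
  cfg <- tinyConfig()
  set.seed(16)
  x <- array(stats::rnorm(8 * 4 * 300), c(8, 4, 300))
  y <- rep(0:4, length.out = 8)
  for (v in c("full", "no_msconv", "eeg_only", "no_se", "no_lstm", "no_attn")) {
    m <- buildVariant(v, cfg, seed = 17)
    set.seed(18)
    fw <- sleepnet:::sleepNetForward(m, x, training = TRUE)
    xe <- sleepnet:::xentFromLogits(fw$logits, y)
    grads <- sleepnet:::sleepNetBackward(m, fw, xe$dlogits)
    st <- sleepnet:::adamInit(m@params)
    upd <- sleepnet:::adamStep(m@params, grads, st, lr = 1e-3)
    m2 <- m
    m2@params <- upd$params
    m2@buffers <- fw$buffers
    set.seed(18) # same dropout masks: isolate the parameter update
    fw2 <- sleepnet:::sleepNetForward(m2, x, training = TRUE)
    l2 <- sleepnet:::xentFromLogits(fw2$logits, y)$loss
    expect_lt(l2, xe$loss)
  }
})

test_that("backpropagation matches central finite differences", {
  cfg <- tinyConfig(convDropout = 0, classifierDropout = 0)
  set.seed(55)
  x <- array(stats::rnorm(3 * 4 * 300), c(3, 4, 300))
  y <- c(0L, 2L, 4L)
  lossOf <- function(m) {
    fw <- sleepnet:::sleepNetForward(m, x, training = TRUE)
    sleepnet:::xentFromLogits(fw$logits, y)$loss
  }
  eps <- 1e-5
  for (v in c("full", "no_lstm")) {
    m <- buildVariant(v, cfg, seed = 56)
    fw <- sleepnet:::sleepNetForward(m, x, training = TRUE)
    xe <- sleepnet:::xentFromLogits(fw$logits, y)
    grads <- sleepnet:::sleepNetBackward(m, fw, xe$dlogits)
    for (nm in names(grads)) {
      # skip the conv bias: batch norm makes the loss exactly invariant to
      # it, so both gradients are ~0 and relative error is meaningless
      if (grepl("convB", nm)) next
      p <- m@params[[nm]]
      for (i in sample(length(p), min(3, length(p)))) {
        m2 <- m
        m2@params[[nm]][i] <- p[i] + eps
        lp <- lossOf(m2)
        m2@params[[nm]][i] <- p[i] - eps
        lm <- lossOf(m2)
        num <- (lp - lm) / (2 * eps)
        ana <- grads[[nm]][i]
        expect_lt(
          abs(num - ana) / max(1e-6, abs(num) + abs(ana)),
          1e-4
        )
      }
    }
  }
})

test_that("checkpoints round-trip through disk", {
  m <- buildVariant("full", tinyConfig(), seed = 19)
  path <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(m, path)
  m2 <- loadCheckpoint(path)
  expect_identical(m2@params, m@params)
  expect_identical(m2@config, m@config)
  expect_identical(variantName(m2), "full")
  set.seed(20)
  x <- array(stats::rnorm(1 * 4 * 300), c(1, 4, 300))
  expect_identical(predictStages(m, x), predictStages(m2, x))
})
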