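# Model assembly: configuration, the six architecture variants, and the full
# forward / backward passes.
#
# Architecture (default configuration): each modality (EEG with its two
# derivations as input channels, EOG, EMG) passes through a dual-branch 1-d
# convolutional block — a small kernel (50 samples, stride 6, max pool 8)
# capturing sub-second transients and a large kernel (400 samples, ~4 s
# receptive field, stride 50, max pool 4) capturing slow-wave trends — each
# branch ordered conv -> batch norm -> LeakyReLU -> max pool -> dropout.
# Branch outputs are concatenated along the time axis (61 + 13 = 74 steps),
# gated per modality by a squeeze-and-excitation channel attention, then the
# three modality maps are concatenated along the feature axis (3 x 64 = 192)
# and rearranged to (time, features) for a single-layer BiLSTM (128 hidden
# units per direction). Attention pooling over the 74 bidirectional states
# yields the context vector, which after dropout feeds a 5-way softmax.

#' Architecture configuration
#'
#' All tunable architecture hyperparameters with their defaults. Kernels,
#' strides and pools are in samples at 100 Hz; the small/large strides and
#' pools are chosen so the two branch output lengths (61 and 13 steps) are
#' the same order of magnitude, which keeps the time-axis concatenation
#' meaningful.
#'
#' @param smallKernel,largeKernel convolution kernel lengths (50, 400).
#' @param filters convolution filters per branch (64, equal across branches
#'   so the time-axis concatenation is well defined).
#' @param smallStride,largeStride convolution strides (6, 50).
#' @param smallPool,largePool max-pool widths (8, 4).
#' @param convDropout dropout after each conv branch (0.5).
#' @param leakySlope LeakyReLU negative slope (0.01).
#' @param seReduction squeeze-and-excitation bottleneck ratio r (4); must
#'   divide `filters`.
#' @param lstmHidden hidden units per LSTM direction (128).
#' @param attentionWidth width of the attention scoring layer (128).
#' @param classifierDropout dropout on the context vector (0.5).
#' @param nClasses number of sleep stages (5).
#' @param samplesPerEpoch input samples per epoch (3000 = 30 s at 100 Hz).
#' @return a validated named list, class `"ModelConfig"`.
#' @export
sleepNetConfig <- function(smallKernel = 50, largeKernel = 400, filters = 64,
                           smallStride = 6, largeStride = 50,
                           smallPool = 8, largePool = 4,
                           convDropout = 0.5, leakySlope = 0.01,
                           seReduction = 4, lstmHidden = 128,
                           attentionWidth = 128, classifierDropout = 0.5,
                           nClasses = 5, samplesPerEpoch = 3000) {
  cfg <- list(
    smallKernel = smallKernel, largeKernel = largeKernel, filters = filters,
    smallStride = smallStride, largeStride = largeStride,
    smallPool = smallPool, largePool = largePool,
    convDropout = convDropout, leakySlope = leakySlope,
    seReduction = seReduction, lstmHidden = lstmHidden,
    attentionWidth = attentionWidth, classifierDropout = classifierDropout,
    nClasses = nClasses, samplesPerEpoch = samplesPerEpoch
  )
  if (smallKernel >= samplesPerEpoch || largeKernel >= samplesPerEpoch) {
    stopf("kernels must be shorter than the %d-sample epoch", samplesPerEpoch)
  }
  if (filters %% seReduction != 0) {
    stopf("seReduction (%d) must divide filters (%d)", seReduction, filters)
  }
  structure(cfg, class = "ModelConfig")
}

.VARIANTS <- c("full", "no_msconv", "eeg_only", "no_se", "no_lstm", "no_attn")

convOutLen <- function(lin, kernel, stride, pool) {
  ((lin - kernel) %/% stride + 1L) %/% pool
}

# Static layout of a variant: which modalities/branches/modules exist and
# every derived dimension.
.variantLayout <- function(variant, cfg) {
  mods <- if (variant == "eeg_only") {
    list(eeg = 1:2)
  } else {
    list(eeg = 1:2, eog = 3L, emg = 4L)
  }
  branches <- if (variant == "no_msconv") "small" else c("small", "large")
  lSmall <- convOutLen(cfg$samplesPerEpoch, cfg$smallKernel, cfg$smallStride,
    cfg$smallPool)
  lLarge <- convOutLen(cfg$samplesPerEpoch, cfg$largeKernel, cfg$largeStride,
    cfg$largePool)
  tSeq <- if (variant == "no_msconv") lSmall else lSmall + lLarge
  featDim <- cfg$filters * length(mods)
  hasSE <- variant != "no_se"
  hasLSTM <- variant != "no_lstm"
  hasAttn <- variant != "no_attn"
  ctxDim <- if (hasLSTM) 2L * cfg$lstmHidden else featDim
  list(
    mods = mods, branches = branches, lSmall = lSmall, lLarge = lLarge,
    tSeq = tSeq, featDim = featDim, hasSE = hasSE, hasLSTM = hasLSTM,
    hasAttn = hasAttn, ctxDim = ctxDim,
    nInputChannels = max(unlist(mods))
  )
}

#' Build a model variant
#'
#' Constructs one of the six architecture variants with freshly initialized
#' parameters (uniform fan-in scheme, deterministic under `seed`):
#' \describe{
#'   \item{full}{the complete architecture.}
#'   \item{no_msconv}{small-kernel branch only (time axis 61 steps).}
#'   \item{eeg_only}{EEG input only; EOG/EMG branches absent, feature width
#'     64 and the LSTM resized accordingly.}
#'   \item{no_se}{squeeze-and-excitation replaced by identity.}
#'   \item{no_lstm}{BiLSTM removed; attention pooling applied directly over
#'     the convolutional feature sequence.}
#'   \item{no_attn}{BiLSTM retained; the context vector is the last time
#'     step's bidirectional state.}
#' }
#'
#' @param variant one of `"full"`, `"no_msconv"`, `"eeg_only"`, `"no_se"`,
#'   `"no_lstm"`, `"no_attn"`.
#' @param config a [sleepNetConfig()].
#' @param seed integer seed for parameter initialization.
#' @return a [SleepNetModel-class].
#' @export
buildVariant <- function(variant = "full", config = sleepNetConfig(),
                         seed = 42) {
  if (!variant %in% .VARIANTS) {
    stopf(
      "unknown variant '%s'; valid variants: %s",
      variant, paste(.VARIANTS, collapse = ", ")
    )
  }
  lay <- .variantLayout(variant, config)
  set.seed(seed)
  params <- list()
  buffers <- list()
  Fn <- config$filters
  for (m in names(lay$mods)) {
    cin <- length(lay$mods[[m]])
    for (br in lay$branches) {
      k <- if (br == "small") config$smallKernel else config$largeKernel
      fanIn <- cin * k
      params[[paste0(m, ".", br, ".convW")]] <- initUniform(Fn, fanIn, fanIn)
      params[[paste0(m, ".", br, ".convB")]] <- initUniformVec(Fn, fanIn)
      params[[paste0(m, ".", br, ".bnG")]] <- rep(1, Fn)
      params[[paste0(m, ".", br, ".bnB")]] <- rep(0, Fn)
      buffers[[paste0(m, ".", br, ".rm")]] <- rep(0, Fn)
      buffers[[paste0(m, ".", br, ".rv")]] <- rep(1, Fn)
    }
    if (lay$hasSE) {
      r <- Fn %/% config$seReduction
      params[[paste0(m, ".se.W1")]] <- initUniform(r, Fn, Fn)
      params[[paste0(m, ".se.W2")]] <- initUniform(Fn, r, r)
    }
  }
  if (lay$hasLSTM) {
    H <- config$lstmHidden
    for (dir in c("f", "b")) {
      params[[paste0("lstm.", dir, ".Wx")]] <- initUniform(4 * H, lay$featDim, H)
      params[[paste0("lstm.", dir, ".Wh")]] <- initUniform(4 * H, H, H)
      params[[paste0("lstm.", dir, ".b")]] <- initUniformVec(4 * H, H)
    }
  }
  if (lay$hasAttn) {
    A <- config$attentionWidth
    params[["attn.Wh"]] <- initUniform(A, lay$ctxDim, lay$ctxDim)
    params[["attn.bh"]] <- initUniformVec(A, lay$ctxDim)
    params[["attn.v"]] <- initUniformVec(A, A)
  }
  params[["fc.W"]] <- initUniform(config$nClasses, lay$ctxDim, lay$ctxDim)
  params[["fc.b"]] <- initUniformVec(config$nClasses, lay$ctxDim)

  new("SleepNetModel",
    variant = variant, config = unclass(config),
    params = params, buffers = buffers, trained = FALSE
  )
}

# One conv branch: conv -> BN -> LeakyReLU (fused) -> max pool -> dropout.
.branchForward <- function(x, params, buffers, prefix, kernel, stride, pool,
                           cfg, training) {
  cv <- convForward(x, params[[paste0(prefix, ".convW")]],
    params[[paste0(prefix, ".convB")]], kernel, stride,
    keepCache = training)
  d <- dim(cv$out)
  xm <- cv$out
  dim(xm) <- c(d[1], d[2] * d[3])
  bn <- bnLeakyForward(xm, params[[paste0(prefix, ".bnG")]],
    params[[paste0(prefix, ".bnB")]],
    buffers[[paste0(prefix, ".rm")]], buffers[[paste0(prefix, ".rv")]],
    training, cfg$leakySlope)
  act <- bn$out
  dim(act) <- d
  mp <- maxpoolForward(act, pool)
  dr <- dropoutForward(mp$out, cfg$convDropout, training)
  list(
    out = dr$out, convCache = if (training) cv$xc, bn = if (training) bn,
    mp = if (training) mp, dropMask = dr$mask, convDim = d,
    outLen = dim(mp$out)[2],
    rm = bn$rm, rv = bn$rv
  )
}

.branchBackward <- function(dout, cache, params, prefix, cfg) {
  dmp <- dropoutBackward(dout, cache$dropMask)
  dact <- maxpoolBackward(dmp, cache$mp)
  d <- cache$convDim
  dim(dact) <- c(d[1], d[2] * d[3])
  bb <- bnLeakyBackward(dact, cache$bn$out,
    params[[paste0(prefix, ".bnG")]], cache$bn$xhat, cache$bn$invstd,
    cfg$leakySlope)
  dconv <- bb$dx
  dim(dconv) <- d
  cb <- convBackward(dconv, cache$convCache)
  grads <- list()
  grads[[paste0(prefix, ".convW")]] <- cb$dW
  grads[[paste0(prefix, ".convB")]] <- as.vector(cb$db)
  grads[[paste0(prefix, ".bnG")]] <- as.vector(bb$dg)
  grads[[paste0(prefix, ".bnB")]] <- as.vector(bb$db)
  grads
}

# Full forward pass. x: (B, C, samples) numeric array (epoch-set layout).
# Returns logits plus, when training, every cache needed for the backward
# pass; buffers are the updated batch-norm running statistics.
sleepNetForward <- function(model, x, training = FALSE) {
  cfg <- model@config
  lay <- .variantLayout(model@variant, cfg)
  d <- dim(x)
  if (d[2] < lay$nInputChannels) {
    stopf(
      "variant '%s' needs %d input channels, got %d",
      model@variant, lay$nInputChannels, d[2]
    )
  }
  B <- d[1]
  params <- model@params
  buffers <- model@buffers
  x3 <- aperm(x, c(2, 3, 1)) # (C, samples, B)

  modCaches <- list()
  feats <- NULL
  for (m in names(lay$mods)) {
    xm <- x3[lay$mods[[m]], , , drop = FALSE]
    brCaches <- list()
    brOuts <- list()
    for (br in lay$branches) {
      k <- if (br == "small") cfg$smallKernel else cfg$largeKernel
      st <- if (br == "small") cfg$smallStride else cfg$largeStride
      pl <- if (br == "small") cfg$smallPool else cfg$largePool
      prefix <- paste0(m, ".", br)
      bc <- .branchForward(xm, params, buffers, prefix, k, st, pl, cfg, training)
      if (training) {
        buffers[[paste0(prefix, ".rm")]] <- as.vector(bc$rm)
        buffers[[paste0(prefix, ".rv")]] <- as.vector(bc$rv)
      }
      brCaches[[br]] <- bc
      brOuts[[br]] <- bc$out
    }
    # concatenate branch outputs along the time axis, small first
    merged <- if (length(brOuts) == 1L) {
      brOuts[[1]]
    } else {
      dm <- dim(brOuts$small)
      dl <- dim(brOuts$large)
      out <- array(0, c(dm[1], dm[2] + dl[2], B))
      out[, seq_len(dm[2]), ] <- brOuts$small
      out[, dm[2] + seq_len(dl[2]), ] <- brOuts$large
      out
    }
    seCache <- NULL
    if (lay$hasSE) {
      seCache <- seForward(merged, params[[paste0(m, ".se.W1")]],
        params[[paste0(m, ".se.W2")]])
      gated <- seCache$out
    } else {
      gated <- merged
    }
    modCaches[[m]] <- list(branches = brCaches, merged = merged, se = seCache)
    feats <- if (is.null(feats)) gated else {
      tmp <- array(0, c(dim(feats)[1] + dim(gated)[1], dim(gated)[2], B))
      tmp[seq_len(dim(feats)[1]), , ] <- feats
      tmp[dim(feats)[1] + seq_len(dim(gated)[1]), , ] <- gated
      tmp
    }
  }
  # feats: (featDim, tSeq, B)

  lstmF <- lstmB <- NULL
  if (lay$hasLSTM) {
    lstmF <- lstmDirForward(feats, params[["lstm.f.Wx"]], params[["lstm.f.Wh"]],
      params[["lstm.f.b"]])
    lstmB <- lstmDirForward(feats, params[["lstm.b.Wx"]], params[["lstm.b.Wh"]],
      params[["lstm.b.b"]], reverse = TRUE)
    H <- cfg$lstmHidden
    hs <- array(0, c(2 * H, lay$tSeq, B))
    hs[seq_len(H), , ] <- lstmF$hs
    hs[H + seq_len(H), , ] <- lstmB$hs
  } else {
    hs <- feats
  }

  attnCache <- NULL
  if (lay$hasAttn) {
    attnCache <- attnForward(hs, params[["attn.Wh"]], params[["attn.bh"]],
      params[["attn.v"]])
    ctx <- attnCache$ctx
    alpha <- attnCache$alpha
  } else {
    ctx <- matrix(hs[, lay$tSeq, ], lay$ctxDim, B)
    alpha <- NULL
  }

  drop <- dropoutForward(ctx, cfg$classifierDropout, training)
  logits <- params[["fc.W"]] %*% drop$out + params[["fc.b"]]

  list(
    logits = logits, alpha = alpha, feats = feats, buffers = buffers,
    cache = if (training) {
      list(
        lay = lay, modCaches = modCaches, feats = feats, hs = hs,
        lstmF = lstmF, lstmB = lstmB, attn = attnCache, ctx = ctx,
        ctxDrop = drop, B = B
      )
    }
  )
}

# Backward pass from dlogits; returns the gradient list (same names as
# params).
sleepNetBackward <- function(model, fw, dlogits) {
  cfg <- model@config
  params <- model@params
  cache <- fw$cache
  lay <- cache$lay
  B <- cache$B
  grads <- list()

  grads[["fc.W"]] <- dlogits %*% t(cache$ctxDrop$out)
  grads[["fc.b"]] <- rowSums(dlogits)
  dctxDrop <- crossprod(params[["fc.W"]], dlogits)
  dctx <- dropoutBackward(dctxDrop, cache$ctxDrop$mask)

  if (lay$hasAttn) {
    ab <- attnBackward(dctx, cache$hs, params[["attn.Wh"]], params[["attn.v"]],
      cache$attn)
    dhs <- ab$dhs
    grads[["attn.Wh"]] <- ab$dWh
    grads[["attn.bh"]] <- ab$dbh
    grads[["attn.v"]] <- ab$dv
  } else {
    dhs <- array(0, dim(cache$hs))
    dhs[, lay$tSeq, ] <- dctx
  }

  if (lay$hasLSTM) {
    H <- cfg$lstmHidden
    lbF <- lstmDirBackward(dhs[seq_len(H), , , drop = FALSE],
      params[["lstm.f.Wx"]], params[["lstm.f.Wh"]], cache$lstmF)
    lbB <- lstmDirBackward(dhs[H + seq_len(H), , , drop = FALSE],
      params[["lstm.b.Wx"]], params[["lstm.b.Wh"]], cache$lstmB)
    grads[["lstm.f.Wx"]] <- lbF$dWx
    grads[["lstm.f.Wh"]] <- lbF$dWh
    grads[["lstm.f.b"]] <- lbF$db
    grads[["lstm.b.Wx"]] <- lbB$dWx
    grads[["lstm.b.Wh"]] <- lbB$dWh
    grads[["lstm.b.b"]] <- lbB$db
    dfeats <- lbF$dx + lbB$dx
  } else {
    dfeats <- dhs
  }

  off <- 0L
  for (m in names(lay$mods)) {
    mc <- cache$modCaches[[m]]
    Fn <- cfg$filters
    dmod <- dfeats[off + seq_len(Fn), , , drop = FALSE]
    off <- off + Fn
    if (lay$hasSE) {
      sb <- seBackward(dmod, mc$merged, params[[paste0(m, ".se.W1")]],
        params[[paste0(m, ".se.W2")]], mc$se)
      grads[[paste0(m, ".se.W1")]] <- sb$dW1
      grads[[paste0(m, ".se.W2")]] <- sb$dW2
      dmerged <- sb$dx
    } else {
      dmerged <- dmod
    }
    for (br in lay$branches) {
      prefix <- paste0(m, ".", br)
      bc <- mc$branches[[br]]
      lb <- dim(bc$out)[2]
      dbr <- if (br == "small") {
        dmerged[, seq_len(lb), , drop = FALSE]
      } else {
        dmerged[, lay$lSmall + seq_len(lb), , drop = FALSE]
      }
      grads <- c(grads, .branchBackward(dbr, bc, params, prefix, cfg))
    }
  }
  grads
}

#' Multimodal feature-extraction forward pass
#'
#' Runs the convolutional front end only (dual-branch convolutions,
#' time-axis concatenation, per-modality squeeze-and-excitation gating,
#' cross-modality feature concatenation) and returns the fused sequence in
#' (batch, time, features) order. Evaluation mode: dropout off, running
#' batch-norm statistics.
#'
#' @param model a [SleepNetModel-class].
#' @param x numeric array (batch, channels, samples).
#' @return numeric array (batch, timeSteps, features).
#' @export
mfemForward <- function(model, x) {
  fw <- sleepNetForward(model, x, training = FALSE)
  aperm(fw$feats, c(3, 2, 1))
}

#' Squeeze-and-excitation channel attention
#'
#' Gates each feature channel by a sigmoid weight derived from its global
#' average over time: squeeze `z_c = mean_t X[c, t]`, excite
#' `s = sigmoid(W2 relu(W1 z))`, scale `X_hat[c, ] = X[c, ] * s_c`. Gates lie
#' strictly in (0, 1); with zero weights the gate is exactly 0.5 everywhere.
#'
#' @param x numeric array (channels, time, batch) — a matrix (channels,
#'   time) is treated as batch 1.
#' @param W1 bottleneck weights (channels/r x channels).
#' @param W2 expansion weights (channels x channels/r).
#' @return list with `out` (gated features, same shape as `x`) and `gates`
#'   (channels x batch).
#' @export
seLayer <- function(x, W1, W2) {
  squeeze <- is.matrix(x)
  if (squeeze) dim(x) <- c(dim(x), 1L)
  fw <- seForward(x, W1, W2)
  out <- fw$out
  if (squeeze) dim(out) <- dim(out)[1:2]
  list(out = out, gates = fw$s)
}

#' Attention pooling over a hidden-state sequence
#'
#' Scores each time step with `e_t = v' tanh(Wh h_t + bh)`, normalizes the
#' scores with a softmax over time (weights sum to 1 per sample), and
#' returns the convex combination `c = sum_t alpha_t h_t`.
#'
#' @param hs numeric array (stateDim, time, batch) — a matrix (stateDim,
#'   time) is treated as batch 1.
#' @param Wh,bh,v attention parameters (width x stateDim, width, width).
#' @return list with `context` (stateDim x batch) and `alpha` (time x
#'   batch).
#' @export
attentionPool <- function(hs, Wh, bh, v) {
  if (is.matrix(hs)) dim(hs) <- c(dim(hs), 1L)
  fw <- attnForward(hs, Wh, bh, v)
  list(context = fw$ctx, alpha = fw$alpha)
}

#' Classifier head on a context vector
#'
#' Applies dropout (training mode only) and the fully connected softmax
#' layer. In evaluation mode the output is deterministic; probabilities sum
#' to 1 per sample.
#'
#' @param ctx numeric matrix (contextDim, batch).
#' @param W,b classifier weights (nClasses x contextDim) and bias.
#' @param dropout dropout probability in training mode.
#' @param training logical.
#' @return probability matrix (nClasses, batch).
#' @export
classifyContext <- function(ctx, W, b, dropout = 0.5, training = FALSE) {
  dr <- dropoutForward(ctx, dropout, training)
  softmaxCols(W %*% dr$out + b)
}

#' Cross-entropy loss over predicted stage probabilities
#'
#' Mean over the batch of `-log p(true class)`, computed from logits by
#' log-sum-exp so a vanishing probability at the true class never produces
#' `log(0)`. With class weights, each sample's term is multiplied by the
#' weight of its true class.
#'
#' @param logits numeric matrix (nClasses, batch).
#' @param labels integer stage codes (0-based).
#' @param classWeights optional numeric vector of length nClasses.
#' @return scalar loss.
#' @export
crossEntropyLoss <- function(logits, labels, classWeights = NULL) {
  xentFromLogits(logits, labels, classWeights)$loss
}

#' Predict sleep stages for an epoch set
#'
#' Evaluation-mode forward pass in mini-batches.
#'
#' @param model a trained [SleepNetModel-class].
#' @param epochs a [SleepEpochSet-class] (or plain (n, channels, samples)
#'   array).
#' @param batchSize mini-batch size.
#' @param returnProbs also return the probability matrix.
#' @return integer stage codes, or (if `returnProbs`) a list with `labels`,
#'   `probs` (n x 5) and `alpha` attention weights (n x timeSteps, when the
#'   variant has attention pooling).
#' @export
predictStages <- function(model, epochs, batchSize = 128, returnProbs = FALSE) {
  x <- if (methods::is(epochs, "SleepEpochSet")) epochSignals(epochs) else epochs
  n <- dim(x)[1]
  probs <- matrix(0, n, model@config$nClasses)
  alpha <- NULL
  for (i0 in seq(1, n, by = batchSize)) {
    i1 <- min(i0 + batchSize - 1, n)
    fw <- sleepNetForward(model, x[i0:i1, , , drop = FALSE], training = FALSE)
    probs[i0:i1, ] <- t(softmaxCols(fw$logits))
    if (returnProbs && !is.null(fw$alpha)) {
      if (is.null(alpha)) alpha <- matrix(0, n, nrow(fw$alpha))
      alpha[i0:i1, ] <- t(fw$alpha)
    }
  }
  labels <- max.col(probs, ties.method = "first") - 1L
  if (returnProbs) list(labels = labels, probs = probs, alpha = alpha) else labels
}

#' Save / load a model checkpoint
#'
#' Single-file archive embedding the variant, the full configuration, the
#' parameters and the batch-norm running statistics.
#'
#' @param model a [SleepNetModel-class].
#' @param path file path.
#' @return `saveCheckpoint`: the path, invisibly. `loadCheckpoint`: the
#'   model.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(
    variant = model@variant, config = model@config,
    params = model@params, buffers = model@buffers, trained = model@trained
  ), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  new("SleepNetModel",
    variant = x$variant, config = x$config, params = x$params,
    buffers = x$buffers, trained = x$trained
  )
}
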