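# Training protocol: subject-disjoint k-fold cross-validation, stratified
# validation holdout, Adam optimization with early stopping on validation
# loss, checkpointing of the best state.

#' Subject-disjoint cross-validation folds
#'
#' Randomly partitions the subject set into k test folds of sizes differing
#' by at most one; each fold's training set is every other subject. All of a
#' subject's recordings travel together, so no individual contributes to
#' both training and testing.
#'
#' @param subjectIds character vector of subject IDs (duplicates collapsed).
#' @param k number of folds (default 5).
#' @param seed integer seed; the plan is deterministic given the seed.
#' @return a [FoldPlan-class].
#' @export
makeSubjectFolds <- function(subjectIds, k = 5, seed = 1) {
  subjects <- unique(subjectIds)
  if (length(subjects) < k) {
    stopf("need at least k=%d subjects, got %d", k, length(subjects))
  }
  set.seed(seed)
  shuffled <- sample(subjects)
  sizes <- rep(length(subjects) %/% k, k)
  extra <- length(subjects) %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  folds <- vector("list", k)
  at <- 0L
  for (i in seq_len(k)) {
    test <- shuffled[(at + 1):(at + sizes[i])]
    folds[[i]] <- list(train = setdiff(shuffled, test), test = test)
    at <- at + sizes[i]
  }
  new("FoldPlan", k = as.integer(k), seed = as.integer(seed), folds = folds)
}

#' Hold out a validation fraction of training epochs
#'
#' Stratified by class: within each stage, `round(fraction * n_k)` epochs go
#' to validation (at least one when the stage has two or more epochs). N1
#' scarcity makes unstratified small holdouts unstable, which is why
#' stratification is the default.
#'
#' @param labels integer stage codes of the training epochs.
#' @param fraction validation fraction in (0, 1), default 0.10.
#' @param seed integer seed.
#' @param stratify stratify by class (default TRUE).
#' @return list with integer index vectors `train` and `validation`
#'   (disjoint, union = all input indices).
#' @export
splitValidation <- function(labels, fraction = 0.10, seed = 1,
                            stratify = TRUE) {
  if (!(fraction > 0 && fraction < 1)) {
    stopf("fraction must be in (0, 1), got %g", fraction)
  }
  n <- length(labels)
  set.seed(seed)
  if (stratify) {
    val <- integer(0)
    for (cls in unique(labels)) {
      ix <- which(labels == cls)
      nv <- round(fraction * length(ix))
      if (nv == 0 && length(ix) >= 2) nv <- 1L
      if (nv > 0) val <- c(val, sample(ix, nv))
    }
  } else {
    val <- sample(n, round(fraction * n))
  }
  val <- sort(val)
  list(train = setdiff(seq_len(n), val), validation = val)
}

# ---- Adam ------------------------------------------------------------------

adamInit <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Inverse-frequency class weights
#'
#' `w_k = N / (K * N_k)` over the stages present; useful against the strong
#' N1 imbalance. Off by default in training (the plain unweighted
#' cross-entropy is the reference objective).
#'
#' @param labels integer stage codes.
#' @param nClasses number of classes.
#' @return numeric weight vector of length `nClasses`.
#' @export
inverseFrequencyWeights <- function(labels, nClasses = 5) {
  nk <- tabulate(labels + 1L, nbins = nClasses)
  w <- length(labels) / (nClasses * pmax(nk, 1))
  w[nk == 0] <- 0
  w
}

# Mean loss / accuracy of a model on an epoch set (evaluation mode).
evaluateModel <- function(model, x, labels, batchSize = 128,
                          classWeights = NULL) {
  n <- dim(x)[1]
  totalLoss <- 0
  correct <- 0
  for (i0 in seq(1, n, by = batchSize)) {
    i1 <- min(i0 + batchSize - 1, n)
    fw <- sleepNetForward(model, x[i0:i1, , , drop = FALSE], training = FALSE)
    xe <- xentFromLogits(fw$logits, labels[i0:i1], classWeights)
    totalLoss <- totalLoss + xe$loss * (i1 - i0 + 1)
    correct <- correct + sum(max.col(t(fw$logits)) - 1L == labels[i0:i1])
  }
  list(loss = totalLoss / n, acc = correct / n)
}

#' Train a model with Adam and early stopping
#'
#' Mini-batch Adam (learning rate 0.001, batch size 64 by default), batches
#' reshuffled every optimizer epoch with a per-epoch derived seed, the last
#' partial batch kept. Validation loss is monitored after every epoch; the
#' parameters at the best value are kept, and training stops when the loss
#' has not improved for `patience` successive epochs or at `maxEpochs`.
#'
#' @param model an untrained [SleepNetModel-class] from [buildVariant()].
#' @param epochs a normalized [SleepEpochSet-class] of training data.
#' @param valEpochs optional validation [SleepEpochSet-class]; if `NULL`, a
#'   stratified `valFraction` holdout is taken from `epochs`.
#' @param lr,batchSize,maxEpochs,patience optimizer protocol (0.001, 64,
#'   100, 5).
#' @param valFraction validation fraction when `valEpochs` is NULL.
#' @param classWeights `TRUE` for inverse-frequency weights, or a numeric
#'   vector, or `NULL`/`FALSE` for unweighted loss.
#' @param seed master seed (shuffling, dropout, holdout).
#' @param maxSteps optional cap on total optimizer steps.
#' @param stopAtTrainAcc optional early exit when the running training
#'   accuracy of an epoch reaches this value.
#' @param verbose print per-epoch progress.
#' @return list with `model` (best checkpoint, trained flag set), `log`
#'   (data.frame: epoch, split, loss, acc), `bestValLoss`, `stepsUsed`.
#' @export
fitSleepNet <- function(model, epochs, valEpochs = NULL, lr = 1e-3,
                        batchSize = 64, maxEpochs = 100, patience = 5,
                        valFraction = 0.10, classWeights = NULL, seed = 1,
                        maxSteps = NULL, stopAtTrainAcc = NULL,
                        verbose = FALSE) {
  x <- epochSignals(epochs)
  y <- epochLabels(epochs)
  if (is.null(valEpochs)) {
    sp <- splitValidation(y, valFraction, seed = deriveSeed(seed, 1))
    xv <- x[sp$validation, , , drop = FALSE]
    yv <- y[sp$validation]
    x <- x[sp$train, , , drop = FALSE]
    y <- y[sp$train]
  } else {
    xv <- epochSignals(valEpochs)
    yv <- epochLabels(valEpochs)
  }
  w <- if (isTRUE(classWeights)) {
    inverseFrequencyWeights(y, model@config$nClasses)
  } else if (is.numeric(classWeights)) {
    classWeights
  } else {
    NULL
  }

  params <- model@params
  state <- adamInit(params)
  best <- list(loss = Inf, params = params, buffers = model@buffers)
  sinceBest <- 0L
  steps <- 0L
  log <- list()
  n <- dim(x)[1]

  for (ep in seq_len(maxEpochs)) {
    set.seed(deriveSeed(seed, 1000 + ep))
    order <- sample(n)
    epLoss <- 0
    epCorrect <- 0
    for (i0 in seq(1, n, by = batchSize)) {
      i1 <- min(i0 + batchSize - 1, n)
      ix <- order[i0:i1]
      xb <- x[ix, , , drop = FALSE]
      yb <- y[ix]
      model@params <- params
      fw <- sleepNetForward(model, xb, training = TRUE)
      model@buffers <- fw$buffers
      xe <- xentFromLogits(fw$logits, yb, w)
      if (!is.finite(xe$loss)) {
        stopf(
          "non-finite loss at optimizer epoch %d, batch starting at %d",
          ep, i0
        )
      }
      grads <- sleepNetBackward(model, fw, xe$dlogits)
      upd <- adamStep(params, grads, state, lr = lr)
      params <- upd$params
      state <- upd$state
      steps <- steps + 1L
      epLoss <- epLoss + xe$loss * length(ix)
      epCorrect <- epCorrect + sum(max.col(t(fw$logits)) - 1L == yb)
      if (!is.null(maxSteps) && steps >= maxSteps) break
    }
    model@params <- params
    trainLoss <- epLoss / n
    trainAcc <- epCorrect / n
    val <- evaluateModel(model, xv, yv, classWeights = w)
    log[[length(log) + 1L]] <- data.frame(
      epoch = ep, split = c("train", "validation"),
      loss = c(trainLoss, val$loss), acc = c(trainAcc, val$acc)
    )
    if (verbose) {
      message(sprintf(
        "epoch %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
        ep, trainLoss, trainAcc, val$loss, val$acc
      ))
    }
    if (val$loss < best$loss) {
      best <- list(loss = val$loss, params = params, buffers = model@buffers)
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
    }
    if (sinceBest >= patience) break
    if (!is.null(maxSteps) && steps >= maxSteps) break
    if (!is.null(stopAtTrainAcc) && trainAcc >= stopAtTrainAcc) break
  }

  model@params <- best$params
  model@buffers <- best$buffers
  model@trained <- TRUE
  list(
    model = model, log = do.call(rbind, log), bestValLoss = best$loss,
    stepsUsed = steps
  )
}

#' Subject-disjoint cross-validated training and evaluation
#'
#' For each fold of the plan, trains the requested variant on the training
#' subjects (with a nested stratified validation holdout for early
#' stopping), predicts the held-out test subjects, and pools the per-fold
#' confusion matrices by elementwise summation. Every epoch of the dataset
#' receives exactly one test-time prediction.
#'
#' @param dataset a normalized [SleepEpochSet-class].
#' @param variant architecture variant name.
#' @param config a [sleepNetConfig()].
#' @param k number of folds.
#' @param seed master seed driving the fold plan, initialization, holdouts
#'   and shuffling.
#' @param foldPlan optional pre-built [FoldPlan-class] (e.g. to share one
#'   plan across ablation variants).
#' @param ... passed to [fitSleepNet()] (`lr`, `batchSize`, `maxEpochs`,
#'   `patience`, ...).
#' @return list with `pooled` ([ConfusionMatrix-class]), `perFold` list of
#'   confusion matrices, `predictions` integer vector aligned with the
#'   dataset, `metrics` from [computeMetrics()] on the pooled matrix,
#'   `foldPlan`, and `logs`.
#' @export
runCrossValidation <- function(dataset, variant = "full",
                               config = sleepNetConfig(), k = 5, seed = 1,
                               foldPlan = NULL, ...) {
  if (is.null(foldPlan)) {
    foldPlan <- makeSubjectFolds(subjectIds(dataset), k = k,
      seed = deriveSeed(seed, 7))
  }
  subj <- subjectIds(dataset)
  predictions <- rep(NA_integer_, nEpochs(dataset))
  perFold <- list()
  logs <- list()
  for (i in seq_along(foldPlan@folds)) {
    f <- foldPlan@folds[[i]]
    trIx <- which(subj %in% f$train)
    teIx <- which(subj %in% f$test)
    model <- buildVariant(variant, config, seed = deriveSeed(seed, 100 + i))
    fit <- fitSleepNet(model, dataset[trIx],
      seed = deriveSeed(seed, 200 + i), ...
    )
    predictions[teIx] <- predictStages(fit$model, dataset[teIx])
    perFold[[i]] <- confusionMatrix(epochLabels(dataset)[teIx],
      predictions[teIx])
    logs[[i]] <- fit$log
  }
  pooledCounts <- Reduce(`+`, lapply(perFold, counts))
  pooled <- new("ConfusionMatrix", counts = pooledCounts)
  list(
    pooled = pooled, perFold = perFold, predictions = predictions,
    metrics = computeMetrics(pooled), foldPlan = foldPlan, logs = logs
  )
}

#' Audit a fold plan for subject leakage
#'
#' @param foldPlan a [FoldPlan-class].
#' @param subjectIds per-epoch subject IDs of the dataset.
#' @return number of (fold, subject) leaks; 0 means every fold's test
#'   subjects are absent from its training set and every epoch is tested
#'   exactly once.
#' @export
leakageCount <- function(foldPlan, subjectIds) {
  leaks <- 0L
  seen <- character(0)
  for (f in foldPlan@folds) {
    leaks <- leaks + length(intersect(f$train, f$test))
    leaks <- leaks + length(intersect(seen, f$test))
    seen <- c(seen, f$test)
  }
  leaks + length(setdiff(unique(subjectIds), seen))
}
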