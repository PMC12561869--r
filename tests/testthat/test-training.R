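test_that("subject folds are balanced, disjoint and deterministic", {
  subj <- sprintf("S%02d", 1:20)
  plan <- makeSubjectFolds(subj, k = 5, seed = 3)
  sizes <- vapply(foldAssignments(plan), function(f) length(f$test), integer(1))
  expect_equal(sizes, rep(4L, 5))
  for (f in foldAssignments(plan)) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), subj)
  }
  expect_setequal(unlist(lapply(foldAssignments(plan), `[[`, "test")), subj)
  plan2 <- makeSubjectFolds(subj, k = 5, seed = 3)
  expect_identical(foldAssignments(plan), foldAssignments(plan2))

  # 7 subjects over 5 folds: sizes 2,2,1,1,1
  plan7 <- makeSubjectFolds(sprintf("P%d", 1:7), k = 5, seed = 1)
  sizes7 <- vapply(foldAssignments(plan7), function(f) length(f$test),
    integer(1))
  expect_equal(sort(sizes7, decreasing = TRUE), c(2L, 2L, 1L, 1L, 1L))

  expect_error(makeSubjectFolds(c("a", "b"), k = 5), "at least k")
})

test_that("fold plans never leak subjects", {
  for (seed in 1:5) {
    subj <- sprintf("S%02d", seq_len(5 + seed * 3))
    plan <- makeSubjectFolds(subj, k = 5, seed = seed)
    expect_equal(leakageCount(plan, subj), 0)
  }
})

test_that("validation holdout has the stated size and is a partition", {
  set.seed(4)
  labels <- sample(0:4, 1000, replace = TRUE, prob = c(.3, .06, .4, .1, .14))
  sp <- splitValidation(labels, fraction = 0.10, seed = 5)
  expect_length(sp$validation, 100)
  expect_length(sp$train, 900)
  expect_setequal(c(sp$train, sp$validation), seq_len(1000))
  expect_length(intersect(sp$train, sp$validation), 0)
  # stratification puts ~10% of every class in validation
  for (cls in 0:4) {
    nv <- sum(labels[sp$validation] == cls)
    expect_equal(nv, round(0.1 * sum(labels == cls)), tolerance = 1)
  }
  sp2 <- splitValidation(labels, fraction = 0.10, seed = 5)
  expect_identical(sp, sp2)
  expect_error(splitValidation(labels, fraction = 0), "in \\(0, 1\\)")
  expect_error(splitValidation(labels, fraction = 1), "in \\(0, 1\\)")
})

test_that("early stopping fires after patience epochs without improvement", {
  ds <- memoFixture("tinyTrainSet", function() tinyDataset(4, 30, seed = 21))
  m <- buildVariant("full", tinyConfig(), seed = 22)
  # at zero learning rate only the batch-norm running statistics move, so
  # the validation loss settles quickly and the patience rule must end the
  # run exactly `patience` epochs after the best validation epoch
  fit <- fitSleepNet(m, ds,
    lr = 0, maxEpochs = 50, patience = 3, seed = 23,
    batchSize = 32
  )
  valLog <- fit$log[fit$log$split == "validation", ]
  bestEpoch <- valLog$epoch[which.min(valLog$loss)]
  expect_lt(max(fit$log$epoch), 50)
  expect_equal(max(fit$log$epoch), bestEpoch + 3)
  # improving validation loss keeps training alive to the epoch cap
  fit2 <- fitSleepNet(m, ds,
    lr = 1e-3, maxEpochs = 4, patience = 5, seed = 23,
    batchSize = 32
  )
  expect_equal(max(fit2$log$epoch), 4)
  expect_true(fit2$model@trained)
})

test_that("the saved checkpoint reproduces the logged best validation loss", {
  ds <- memoFixture("tinyTrainSet", function() tinyDataset(4, 30, seed = 21))
  sp <- splitValidation(epochLabels(ds), 0.2, seed = 24)
  tr <- ds[sp$train]
  va <- ds[sp$validation]
  m <- buildVariant("full", tinyConfig(), seed = 25)
  fit <- fitSleepNet(m, tr,
    valEpochs = va, maxEpochs = 3, patience = 5,
    seed = 26, batchSize = 32
  )
  re <- sleepnet:::evaluateModel(
    fit$model, epochSignals(va), epochLabels(va)
  )
  expect_equal(re$loss, fit$bestValLoss, tolerance = 1e-6)
  valLog <- fit$log[fit$log$split == "validation", ]
  expect_equal(min(valLog$loss), fit$bestValLoss, tolerance = 1e-6)
})

test_that("training aborts on a non-finite loss with a diagnostic", {
  ds <- memoFixture("tinyTrainSet", function() tinyDataset(4, 30, seed = 21))
  m <- buildVariant("full", tinyConfig(), seed = 27)
  m@params[["fc.W"]][] <- NaN
  expect_error(
    fitSleepNet(m, ds, maxEpochs = 1, seed = 28),
    "non-finite loss.*batch"
  )
})

test_that("cross-validation predicts every epoch once and is additive", {
  ds <- memoFixture("cvTinySet", function() tinyDataset(5, 24, seed = 29))
  cv <- runCrossValidation(ds,
    variant = "full", config = tinyConfig(), k = 5,
    seed = 30, maxEpochs = 1, batchSize = 32
  )
  expect_false(anyNA(cv$predictions))
  expect_equal(length(cv$predictions), nEpochs(ds))
  expect_equal(sum(counts(cv$pooled)), nEpochs(ds))
  # per-fold matrices sum to the pooled matrix
  expect_equal(Reduce(`+`, lapply(cv$perFold, counts)), counts(cv$pooled))
  # no subject leakage under the plan actually used
  expect_equal(leakageCount(cv$foldPlan, subjectIds(ds)), 0)
})

test_that("identical master seeds reproduce the pooled confusion matrix", {
  ds <- memoFixture("cvTinySet", function() tinyDataset(5, 24, seed = 29))
  cv1 <- runCrossValidation(ds,
    variant = "full", config = tinyConfig(), k = 5,
    seed = 31, maxEpochs = 1, batchSize = 32
  )
  cv2 <- runCrossValidation(ds,
    variant = "full", config = tinyConfig(), k = 5,
    seed = 31, maxEpochs = 1, batchSize = 32
  )
  expect_identical(counts(cv1$pooled), counts(cv2$pooled))
  expect_identical(cv1$predictions, cv2$predictions)
})

test_that("removing EOG/EMG hurts when the REM/wake cue lives there", {
  # signals whose wake and REM EEG are indistinguishable: only the EOG
  # deflections and EMG atonia separate the two stages
  ds <- normalizeEpochs(makeSyntheticDataset(
    4, 60,
    sigModel = stageSignalModel(remEEGDistinct = FALSE), seed = 41
  ))
  subj <- subjectIds(ds)
  teIx <- which(subj == "S01")
  trIx <- which(subj != "S01")
  accOf <- function(variant) {
    m <- buildVariant(variant, seed = 42)
    fit <- fitSleepNet(m, ds[trIx],
      maxEpochs = 6, patience = 10, seed = 43,
      batchSize = 64
    )
    pred <- predictStages(fit$model, ds[teIx])
    truth <- epochLabels(ds)[teIx]
    remw <- truth %in% c(0L, 4L)
    mean(pred[remw] == truth[remw])
  }
  accFull <- accOf("full")
  accEeg <- accOf("eeg_only")
  expect_lt(accEeg, accFull)
})

test_that("inverse-frequency weights compensate the class imbalance", {
  labels <- c(rep(0L, 50), rep(1L, 5), rep(2L, 30), rep(3L, 10), rep(4L, 5))
  w <- inverseFrequencyWeights(labels)
  expect_equal(w, 100 / (5 * c(50, 5, 30, 10, 5)))
  expect_equal(which.max(w), 2)
})
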