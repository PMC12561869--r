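test_that("confusion matrix counts pairs correctly", {
  set.seed(42)
  truth <- sample(0:4, 1000, replace = TRUE)
  pred <- sample(0:4, 1000, replace = TRUE)
  cm <- counts(confusionMatrix(truth, pred))
  for (i in 0:4) {
    for (j in 0:4) {
      expect_equal(cm[i + 1, j + 1], sum(truth == i & pred == j))
    }
  }
  expect_equal(sum(cm), 1000)

  perfect <- confusionMatrix(truth, truth)
  expect_equal(sum(counts(perfect)) - sum(diag(counts(perfect))), 0)
  empty <- confusionMatrix(integer(0), integer(0))
  expect_true(all(counts(empty) == 0))
  expect_error(confusionMatrix(0:3, 0:4), "equal length")
})

test_that("one-vs-rest reduction partitions the total", {
  set.seed(7)
  truth <- sample(0:4, 400, replace = TRUE, prob = c(.4, .05, .3, .1, .15))
  pred <- sample(0:4, 400, replace = TRUE)
  cm <- confusionMatrix(truth, pred)
  for (k in 0:4) {
    b <- oneVsRest(cm, k)
    expect_equal(sum(b), 400)
    expect_equal(unname(b["TP"]), sum(truth == k & pred == k))
    expect_equal(unname(b["FP"]), sum(truth != k & pred == k))
    expect_equal(unname(b["FN"]), sum(truth == k & pred != k))
  }
  diagCm <- confusionMatrix(truth, truth)
  for (k in 0:4) {
    b <- oneVsRest(diagCm, k)
    expect_equal(unname(b["FP"]), 0)
    expect_equal(unname(b["FN"]), 0)
  }
})

test_that("computeMetrics agrees with a brute-force oracle on random matrices", {
  set.seed(123)
  for (rep in 1:200) {
    cm <- matrix(rpois(25, lambda = 20), 5, 5)
    if (sum(cm) == 0) cm[1, 1] <- 1
    labels <- expandConfusion(cm)
    got <- suppressWarnings(
      computeMetrics(confusionMatrix(labels$truth, labels$pred))
    )
    want <- bruteForceMetrics(labels$truth, labels$pred)
    for (f in c("ACC", "F1_Macro", "Kappa", "SEN", "SPE", "PRE")) {
      expect_lt(abs(got[[f]] - want[[f]]), 1e-10)
    }
    expect_true(all(abs(as.matrix(got$perClass[, 2:5]) -
      as.matrix(want$perClass)) < 1e-10))
  }
})

test_that("kappa matches an independent library implementation", {
  skip_if_not_installed("e1071")
  set.seed(99)
  for (rep in 1:10) {
    truth <- sample(0:4, 300, replace = TRUE)
    pred <- sample(0:4, 300, replace = TRUE)
    got <- computeMetrics(confusionMatrix(truth, pred))$Kappa
    ref <- e1071::classAgreement(table(factor(truth, levels = 0:4),
      factor(pred, levels = 0:4)))$kappa
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("worked binary-style example yields the hand-derived ACC and kappa", {
  cm <- matrix(0, 5, 5)
  cm[1:2, 1:2] <- matrix(c(50, 10, 5, 35), 2, 2, byrow = TRUE)
  m <- suppressWarnings(computeMetrics(new("ConfusionMatrix", counts = cm)))
  expect_equal(m$ACC, 0.85, tolerance = 1e-6)
  # Pe = (60*55 + 40*45) / 100^2 = 0.51; kappa = (0.85 - 0.51) / 0.49
  expect_equal(m$Kappa, 0.6938776, tolerance = 1e-6)
})

test_that("metric invariances hold", {
  set.seed(31)
  truth <- sample(0:4, 500, replace = TRUE, prob = c(.3, .05, .35, .15, .15))
  pred <- sample(0:4, 500, replace = TRUE)
  cm <- counts(confusionMatrix(truth, pred))
  m1 <- computeMetrics(new("ConfusionMatrix", counts = cm))
  m7 <- computeMetrics(new("ConfusionMatrix", counts = cm * 7))
  for (f in c("ACC", "F1_Macro", "Kappa", "SEN", "SPE", "PRE")) {
    expect_equal(m1[[f]], m7[[f]], tolerance = 1e-12)
  }
  # ACC is the truth-frequency-weighted mean of per-class sensitivity
  wts <- rowSums(cm) / sum(cm)
  expect_equal(m1$ACC, sum(wts * m1$perClass$SEN), tolerance = 1e-12)
  # degenerate prediction: single predicted class has zero chance-corrected
  # agreement
  mono <- computeMetrics(confusionMatrix(truth, rep(2L, 500)))
  expect_equal(mono$Kappa, 0, tolerance = 1e-12)
  # perfect prediction
  perf <- computeMetrics(confusionMatrix(truth, truth))
  expect_equal(perf$ACC, 1)
  expect_equal(perf$Kappa, 1)
  expect_equal(perf$F1_Macro, 1)
})

test_that("hypnogram traces use the conventional ordinate and invert exactly", {
  labels <- c(0L, 4L, 1L, 2L, 3L, 2L, 0L)
  hs <- hypnogramSeries(labels, labels)
  expect_equal(nrow(hs), length(labels))
  expect_identical(hs$truth, hs$predicted)
  # W above REM above N1 above N2 above N3
  expect_equal(hs$truth, c(5L, 4L, 3L, 2L, 1L, 2L, 5L))
  expect_identical(hypnogramLevelsToStages(hs$truth), labels)
  expect_error(hypnogramSeries(0:3, 0:4), "equal length")
})
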