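test_that("stage-label mapping follows the scoring table", {
  track <- AnnotationTrack(
    onset = c(0, 1800, 1830, 1860, 1890, 1920),
    duration = c(1800, 30, 30, 30, 30, 30),
    label = c(
      "Sleep stage W", "Sleep stage 1", "Sleep stage 2",
      "Sleep stage 3", "Sleep stage 4", "Sleep stage R"
    )
  )
  slots <- mapStageLabels(track)
  expect_equal(length(slots), 65)
  expect_equal(slots[1:60], rep(0L, 60)) # 1800 s of W -> 60 slots
  # N1, N2, then stages 3 and 4 both merging into N3, then REM
  expect_equal(slots[61:65], c(1L, 2L, 3L, 3L, 4L))
})

test_that("movement time and unscored slots are excluded, unknown labels error", {
  track <- AnnotationTrack(
    onset = c(0, 30, 60),
    duration = c(30, 30, 30),
    label = c("Sleep stage 2", "Movement time", "Sleep stage ?")
  )
  expect_equal(mapStageLabels(track), c(2L, -1L, -1L))
  expect_error(
    mapStageLabels(AnnotationTrack(0, 30, "Sleep stage Q")),
    "Sleep stage Q"
  )
})

.constRecording <- function(nSlots, rate = 100, epochSec = 30) {
  n <- nSlots * epochSec * rate
  TimeSeriesRecording("R", "S",
    signals = stats::setNames(
      lapply(1:4, function(i) seq_len(n) + i * 1e6),
      channelOrder()
    ),
    samplingRates = rate
  )
}

test_that("wake trimming keeps a margin around the sleep period", {
  # 2 h all N2, margin 30 -> all 240 slots retained
  rec <- .constRecording(240)
  es <- epochAndTrim(rec, rep(2L, 240), wakeMarginMin = 30)
  expect_equal(nEpochs(es), 240)

  # 3 h of W then 1 h of N2, margin 30 -> 60 W + 120 N2
  rec <- .constRecording(480)
  labels <- c(rep(0L, 360), rep(2L, 120))
  es <- epochAndTrim(rec, labels, wakeMarginMin = 30)
  expect_equal(nEpochs(es), 180)
  expect_equal(sum(epochLabels(es) == 0), 60)
  expect_equal(sum(epochLabels(es) == 2), 120)

  # margin 0 -> wake strictly outside the sleep period dropped
  es0 <- epochAndTrim(rec, labels, wakeMarginMin = 0)
  expect_equal(nEpochs(es0), 120)
  expect_true(all(epochLabels(es0) == 2))

  # wake between sleep episodes survives any margin
  labels2 <- c(rep(2L, 10), rep(0L, 20), rep(2L, 10), rep(0L, 440))
  es2 <- epochAndTrim(rec, labels2, wakeMarginMin = 0)
  expect_equal(nEpochs(es2), 40)

  expect_error(
    epochAndTrim(rec, rep(0L, 480)),
    "no non-wake"
  )
})

test_that("excluded slots are dropped and retained epochs are lossless", {
  rec <- .constRecording(6)
  labels <- c(2L, -1L, 3L, 2L, -1L, 4L)
  es <- epochAndTrim(rec, labels)
  expect_equal(nEpochs(es), 4)
  expect_equal(epochLabels(es), c(2L, 3L, 2L, 4L))
  # epoching is lossless: epoch signals reproduce the source samples
  spe <- 3000
  src <- rec@signals[[1]]
  kept <- which(labels != -1L)
  for (e in seq_along(kept)) {
    expect_equal(
      as.vector(epochSignals(es)[e, 1, ]),
      src[((kept[e] - 1) * spe + 1):(kept[e] * spe)]
    )
  }
  expect_true(all(epochLabels(es) %in% 0:4))
})

test_that("z-score normalization is exact, guarded and idempotent", {
  set.seed(3)
  sig <- array(stats::rnorm(20 * 4 * 300, mean = 5, sd = 7), c(20, 4, 300))
  sig[, 2, ] <- 42 # constant channel
  es <- SleepEpochSet(sig, rep(2L, 20), "S1",
    samplingRate = 100, epochSec = 3
  )
  nz <- normalizeEpochs(es)
  for (ch in c(1, 3, 4)) {
    x <- epochSignals(nz)[, ch, ]
    expect_lt(abs(mean(x)), 1e-6)
    expect_lt(abs(stats::sd(as.vector(x)) - 1), 1e-4)
  }
  expect_true(all(epochSignals(nz)[, 2, ] == 0))
  nz2 <- normalizeEpochs(nz)
  expect_lt(max(abs(epochSignals(nz2) - epochSignals(nz))), 1e-6)
  expect_true(nz@normalized)
})

test_that("epoch sets validate their invariants", {
  sig <- array(0, c(3, 4, 300))
  expect_error(
    SleepEpochSet(sig, c(0L, 1L, 5L), "S1", samplingRate = 100, epochSec = 3),
    "0..4"
  )
  expect_error(
    SleepEpochSet(sig, c(0L, 1L), "S1", samplingRate = 100, epochSec = 3),
    "one label per epoch"
  )
  expect_error(
    SleepEpochSet(sig, c(0L, 1L, 2L), c("", "a", "b"),
      samplingRate = 100, epochSec = 3
    ),
    "non-empty"
  )
  expect_error(
    SleepEpochSet(sig, c(0L, 1L, 2L), "S1", samplingRate = 100, epochSec = 30),
    "samples per epoch"
  )
})
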