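# Shared fixtures and independent oracles. Everything is generated in code;
# expensive fixtures are memoized for the duration of the test run.

.fixtures <- new.env(parent = emptyenv())

memoFixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# A scaled-down architecture on 3 s epochs, for tests of training logic and
# layer mechanics where the full 30 s geometry adds nothing.
tinyConfig <- function(...) {
  sleepNetConfig(
    smallKernel = 20, largeKernel = 60, filters = 8, smallStride = 4,
    largeStride = 20, smallPool = 4, largePool = 2, seReduction = 4,
    lstmHidden = 8, attentionWidth = 8, samplesPerEpoch = 300, ...
  )
}

# Small synthetic epoch set on the 3 s geometry.
tinyDataset <- function(nSubjects = 4, epochsPerSubject = 30, seed = 11) {
  normalizeEpochs(makeSyntheticDataset(
    nSubjects, epochsPerSubject,
    seed = seed, epochSec = 3
  ))
}

# A deterministic 60 s four-channel recording for EDF tests.
demoRecording <- function(rate = 100, durationSec = 60, seed = 8) {
  set.seed(seed)
  t <- (seq_len(rate * durationSec) - 1) / rate
  TimeSeriesRecording(
    "REC1", "S1",
    signals = list(
      "EEG Fpz-Cz" = 20 * sin(2 * pi * 10 * t),
      "EEG Pz-Oz" = stats::rnorm(length(t), sd = 15),
      "EOG horizontal" = 50 * sin(2 * pi * 0.3 * t),
      "EMG submental" = stats::rnorm(length(t), sd = 5)
    ),
    samplingRates = rate
  )
}

# ---- independent metric oracle --------------------------------------------
# Computes every evaluation quantity directly from label vectors by explicit
# counting, sharing no code with computeMetrics().

bruteForceMetrics <- function(truth, pred) {
  n <- length(truth)
  acc <- mean(truth == pred)
  pre <- sen <- spe <- f1 <- numeric(5)
  for (k in 0:4) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    tn <- sum(truth != k & pred != k)
    pre[k + 1] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    sen[k + 1] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    spe[k + 1] <- if (tn + fp == 0) 0 else tn / (tn + fp)
    f1[k + 1] <- if (pre[k + 1] + sen[k + 1] == 0) {
      0
    } else {
      2 * pre[k + 1] * sen[k + 1] / (pre[k + 1] + sen[k + 1])
    }
  }
  pe <- 0
  for (k in 0:4) pe <- pe + mean(truth == k) * mean(pred == k)
  list(
    ACC = acc, F1_Macro = mean(f1), Kappa = (acc - pe) / (1 - pe),
    SEN = mean(sen), SPE = mean(spe), PRE = mean(pre),
    perClass = data.frame(PRE = pre, SEN = sen, SPE = spe, F1 = f1)
  )
}

# Expand a count matrix into the label vectors it summarizes.
expandConfusion <- function(cm) {
  truth <- pred <- integer(0)
  for (i in 1:5) {
    for (j in 1:5) {
      if (cm[i, j] > 0) {
        truth <- c(truth, rep(i - 1L, cm[i, j]))
        pred <- c(pred, rep(j - 1L, cm[i, j]))
      }
    }
  }
  list(truth = truth, pred = pred)
}
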