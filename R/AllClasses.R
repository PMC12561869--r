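# S4 classes for the central data containers.

#' TimeSeriesRecording: one night of multichannel polysomnography
#'
#' Holds the retained channels of a single PSG recording. Signals are stored
#' in physical units (microvolts) as plain numeric vectors, one per channel,
#' together with per-channel sampling rates in Hz. After [resampleRecording()]
#' (applied automatically by [readPSG()]) all channels share a common rate and
#' a common sample count, which is what epoching requires.
#'
#' @slot recordingId character scalar identifying the recording.
#' @slot subjectId character scalar identifying the subject.
#' @slot signals named list of numeric vectors, one per channel, in uV.
#' @slot samplingRates named numeric vector of per-channel rates in Hz.
#' @slot startTime numeric scalar, seconds offset of the first sample
#'   (origin 0).
#'
#' @export
setClass("TimeSeriesRecording",
  representation(
    recordingId = "character",
    subjectId = "character",
    signals = "list",
    samplingRates = "numeric",
    startTime = "numeric"
  ),
  prototype(startTime = 0)
)

setValidity("TimeSeriesRecording", function(object) {
  msg <- character()
  labs <- names(object@signals)
  if (is.null(labs) || anyDuplicated(labs)) {
    msg <- c(msg, "channel labels must be present and unique")
  }
  if (!identical(labs, names(object@samplingRates))) {
    msg <- c(msg, "signals and samplingRates must share names and order")
  }
  if (any(object@samplingRates <= 0)) {
    msg <- c(msg, "sampling rates must be positive")
  }
  if (!all(vapply(object@signals, is.numeric, logical(1)))) {
    msg <- c(msg, "all channel signals must be numeric")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TimeSeriesRecording
#'
#' @param recordingId,subjectId identifiers.
#' @param signals named list of numeric vectors (uV), names are channel
#'   labels.
#' @param samplingRates numeric vector of per-channel rates in Hz; recycled
#'   if length 1.
#' @param startTime seconds offset of first sample.
#' @return a [TimeSeriesRecording-class] object.
#' @export
TimeSeriesRecording <- function(recordingId, subjectId, signals,
                                samplingRates, startTime = 0) {
  if (length(samplingRates) == 1L) {
    samplingRates <- rep(samplingRates, length(signals))
  }
  names(samplingRates) <- names(signals)
  new("TimeSeriesRecording",
    recordingId = as.character(recordingId),
    subjectId = as.character(subjectId),
    signals = signals,
    samplingRates = samplingRates,
    startTime = as.numeric(startTime)
  )
}

#' AnnotationTrack: scored events of one recording
#'
#' One row per scored interval (sleep stage or bookkeeping event), in the
#' hypnogram-annotation dialect used by expanded sleep-cassette archives
#' ("Sleep stage W/1/2/3/4/R/?", "Movement time").
#'
#' @slot events data.frame with columns `onset` (s), `duration` (s),
#'   `label` (character).
#' @export
setClass("AnnotationTrack", representation(events = "data.frame"))

setValidity("AnnotationTrack", function(object) {
  ev <- object@events
  msg <- character()
  if (!all(c("onset", "duration", "label") %in% names(ev))) {
    msg <- c(msg, "events must have columns onset, duration, label")
  } else {
    if (nrow(ev) > 1L && any(diff(ev$onset) < 0)) {
      msg <- c(msg, "event onsets must be non-decreasing")
    }
    if (nrow(ev) > 0L && any(ev$duration <= 0)) {
      msg <- c(msg, "event durations must be positive")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotationTrack
#' @param onset,duration numeric vectors in seconds.
#' @param label character vector of event labels.
#' @return an [AnnotationTrack-class] object.
#' @export
AnnotationTrack <- function(onset = numeric(), duration = numeric(),
                            label = character()) {
  new("AnnotationTrack", events = data.frame(
    onset = as.numeric(onset),
    duration = as.numeric(duration),
    label = as.character(label),
    stringsAsFactors = FALSE
  ))
}

#' SleepEpochSet: labeled 30-second epochs ready for classification
#'
#' The unit of classification is the 30 s epoch. Signals are stored as a
#' numeric array of shape (n_epochs, n_channels, samples_per_epoch); with the
#' default 100 Hz rate and 30 s epochs that is (n, 4, 3000). Labels are the
#' integer stage codes of [stageNames()].
#'
#' @slot signals numeric array (n, channels, samples).
#' @slot labels integer vector of stage codes in 0..4.
#' @slot subjectId,recordingId character vectors, one entry per epoch.
#' @slot channelOrder character vector naming the channel axis.
#' @slot samplingRate numeric scalar, Hz.
#' @slot epochSec numeric scalar, epoch length in seconds.
#' @slot normalized logical scalar; TRUE after per-recording z-scoring.
#' @export
setClass("SleepEpochSet",
  representation(
    signals = "array",
    labels = "integer",
    subjectId = "character",
    recordingId = "character",
    channelOrder = "character",
    samplingRate = "numeric",
    epochSec = "numeric",
    normalized = "logical"
  ),
  prototype(samplingRate = 100, epochSec = 30, normalized = FALSE)
)

setValidity("SleepEpochSet", function(object) {
  d <- dim(object@signals)
  msg <- character()
  if (length(d) != 3L) {
    return("signals must be a 3-d array (epochs, channels, samples)")
  }
  if (d[3] != object@samplingRate * object@epochSec) {
    msg <- c(msg, sprintf(
      "samples per epoch (%d) must equal samplingRate * epochSec (%g)",
      d[3], object@samplingRate * object@epochSec
    ))
  }
  if (length(object@labels) != d[1]) {
    msg <- c(msg, "one label per epoch required")
  }
  if (length(object@labels) && (min(object@labels) < 0L ||
    max(object@labels) > 4L)) {
    msg <- c(msg, "labels must be stage codes in 0..4")
  }
  if (length(object@subjectId) != d[1] || length(object@recordingId) != d[1]) {
    msg <- c(msg, "subjectId and recordingId must have one entry per epoch")
  }
  if (d[1] > 0L && any(!nzchar(object@subjectId))) {
    msg <- c(msg, "subjectId entries must be non-empty")
  }
  if (length(object@channelOrder) != d[2]) {
    msg <- c(msg, "channelOrder must name every channel")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SleepEpochSet
#'
#' @param signals numeric array (n, channels, samples).
#' @param labels integer stage codes (0..4), one per epoch.
#' @param subjectId,recordingId per-epoch identifiers (recycled if scalar).
#' @param channelOrder channel labels; defaults to [channelOrder()].
#' @param samplingRate,epochSec sampling rate (Hz) and epoch length (s).
#' @param normalized whether signals are already z-scored.
#' @return a [SleepEpochSet-class] object.
#' @export
SleepEpochSet <- function(signals, labels, subjectId, recordingId = subjectId,
                          channelOrder = sleepnet::channelOrder(),
                          samplingRate = 100, epochSec = 30,
                          normalized = FALSE) {
  n <- dim(signals)[1]
  if (length(subjectId) == 1L) subjectId <- rep(subjectId, n)
  if (length(recordingId) == 1L) recordingId <- rep(recordingId, n)
  new("SleepEpochSet",
    signals = signals, labels = as.integer(labels),
    subjectId = as.character(subjectId),
    recordingId = as.character(recordingId),
    channelOrder = channelOrder,
    samplingRate = samplingRate, epochSec = epochSec,
    normalized = normalized
  )
}

#' ConfusionMatrix: 5x5 stage-by-stage count matrix
#'
#' Rows are the expert (true) stage, columns the predicted stage. Every
#' evaluation quantity of [computeMetrics()] derives from these counts.
#'
#' @slot counts 5x5 numeric matrix of non-negative integers.
#' @export
setClass("ConfusionMatrix", representation(counts = "matrix"))

setValidity("ConfusionMatrix", function(object) {
  cm <- object@counts
  if (!all(dim(cm) == c(.N_STAGES, .N_STAGES))) {
    return("counts must be a 5x5 matrix")
  }
  if (any(cm < 0) || any(cm != round(cm))) {
    return("counts must be non-negative integers")
  }
  TRUE
})

#' FoldPlan: subject-disjoint cross-validation assignment
#'
#' @slot k integer number of folds.
#' @slot seed integer seed the plan was drawn with.
#' @slot folds list of length k; each element a list with character vectors
#'   `train` and `test` of subject IDs.
#' @export
setClass("FoldPlan",
  representation(k = "integer", seed = "integer", folds = "list")
)

setValidity("FoldPlan", function(object) {
  msg <- character()
  if (length(object@folds) != object@k) {
    msg <- c(msg, "fold list length must equal k")
  }
  testSets <- lapply(object@folds, `[[`, "test")
  allSubj <- sort(unique(unlist(lapply(object@folds, function(f) {
    c(f$train, f$test)
  }))))
  pooledTest <- sort(unlist(testSets))
  if (!identical(pooledTest, allSubj)) {
    msg <- c(msg, "test sets must partition the subject set")
  }
  for (f in object@folds) {
    if (length(intersect(f$train, f$test))) {
      msg <- c(msg, "train and test subjects overlap within a fold")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' SleepNetModel: the multimodal attention sleep-staging network
#'
#' Wraps one architecture variant together with its configuration, trainable
#' parameters and batch-normalization running statistics. Models are built
#' with [buildVariant()], trained with [fitSleepNet()] or
#' [runCrossValidation()], and applied with [predictStages()].
#'
#' @slot variant character; one of `"full"`, `"no_msconv"`, `"eeg_only"`,
#'   `"no_se"`, `"no_lstm"`, `"no_attn"`.
#' @slot config list of architecture hyperparameters, see [sleepNetConfig()].
#' @slot params named list of parameter matrices/vectors.
#' @slot buffers named list of batch-norm running means/variances.
#' @slot trained logical scalar.
#' @export
setClass("SleepNetModel",
  representation(
    variant = "character",
    config = "list",
    params = "list",
    buffers = "list",
    trained = "logical"
  ),
  prototype(trained = FALSE)
)
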