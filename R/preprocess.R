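# Epoching: annotation events -> per-slot stage labels -> labeled 30 s
# epochs with wake trimming and per-recording z-score normalization.

.STAGE_MAP <- c(
  "Sleep stage W" = 0L,
  "Sleep stage 1" = 1L,
  "Sleep stage 2" = 2L,
  "Sleep stage 3" = 3L, # older 4-stage scoring: stages 3 and 4 merge to N3
  "Sleep stage 4" = 3L,
  "Sleep stage R" = 4L,
  "Movement time" = -1L,
  "Sleep stage ?" = -1L
)

#' Map annotation events to per-slot stage labels
#'
#' Divides the annotated span into consecutive 30 s slots and assigns each
#' slot the stage of the event covering it. The older 4-stage deep-sleep
#' scoring is merged into N3; movement time and unscored slots receive the
#' `-1` exclusion sentinel (dropped later by [epochAndTrim()]). Slots not
#' covered by any event are likewise excluded.
#'
#' @param track an [AnnotationTrack-class].
#' @param epochSec slot length in seconds (default 30).
#' @return integer vector of per-slot labels (0..4 or -1), from time 0 to
#'   the end of the last event.
#' @export
mapStageLabels <- function(track, epochSec = 30) {
  ev <- annotationEvents(track)
  if (!nrow(ev)) {
    return(integer(0))
  }
  unknown <- setdiff(unique(ev$label), names(.STAGE_MAP))
  if (length(unknown)) {
    stopf(
      "unknown stage annotation(s): %s",
      paste(sprintf("'%s'", unknown), collapse = ", ")
    )
  }
  nSlots <- ceiling((max(ev$onset + ev$duration)) / epochSec)
  labels <- rep(.EXCLUDED, nSlots)
  for (j in seq_len(nrow(ev))) {
    first <- floor(ev$onset[j] / epochSec) + 1
    nFull <- floor(ev$duration[j] / epochSec)
    if (nFull < 1) next
    labels[first:(first + nFull - 1)] <- .STAGE_MAP[[ev$label[j]]]
  }
  labels
}

#' Cut a recording into labeled epochs with wake trimming
#'
#' Slots labeled with the exclusion sentinel are dropped. Wake epochs more
#' than `wakeMarginMin` minutes before the first non-wake epoch or after the
#' last non-wake epoch are dropped (the conventional in-bed trimming that
#' keeps the class balance from being swamped by pre/post-sleep wake);
#' remaining slots are cut into (channels, samples) blocks aligned to slot
#' onsets. Signals are returned raw; apply [normalizeEpochs()] before
#' training.
#'
#' @param recording a [TimeSeriesRecording-class] with all channels at a
#'   common rate.
#' @param slotLabels integer per-slot labels from [mapStageLabels()].
#' @param wakeMarginMin wake margin in minutes (default 30); 0 keeps only
#'   wake inside the sleep period.
#' @param epochSec epoch length in seconds.
#' @return an unnormalized [SleepEpochSet-class].
#' @export
epochAndTrim <- function(recording, slotLabels, wakeMarginMin = 30,
                         epochSec = 30) {
  rates <- samplingRates(recording)
  if (length(unique(rates)) != 1L) {
    stopf("all channels must share a common sampling rate before epoching")
  }
  rate <- rates[[1]]
  spe <- as.integer(rate * epochSec)
  nChan <- length(recording@signals)
  nSamples <- min(vapply(recording@signals, length, integer(1)))
  nSlots <- min(length(slotLabels), nSamples %/% spe)
  labels <- slotLabels[seq_len(nSlots)]

  keep <- labels != .EXCLUDED
  nonW <- which(labels > 0L & keep)
  if (!length(nonW)) {
    stopf("recording '%s' has no non-wake epochs; nothing anchors wake trimming",
      recording@recordingId)
  }
  marginSlots <- wakeMarginMin * 60 / epochSec
  first <- min(nonW)
  last <- max(nonW)
  isW <- labels == 0L
  slot <- seq_len(nSlots)
  keep <- keep & !(isW & (slot < first - marginSlots | slot > last + marginSlots))

  idx <- which(keep)
  sig <- array(0, dim = c(length(idx), nChan, spe))
  for (e in seq_along(idx)) {
    s0 <- (idx[e] - 1L) * spe
    for (ch in seq_len(nChan)) {
      sig[e, ch, ] <- recording@signals[[ch]][(s0 + 1):(s0 + spe)]
    }
  }
  SleepEpochSet(
    signals = sig, labels = labels[idx],
    subjectId = recording@subjectId, recordingId = recording@recordingId,
    channelOrder = names(recording@signals),
    samplingRate = rate, epochSec = epochSec, normalized = FALSE
  )
}

#' Per-recording, per-channel z-score normalization
#'
#' For each recording and channel, centers and scales all retained samples to
#' mean 0 and standard deviation 1. Constant channels map to all-zeros via an
#' epsilon guard. Idempotent up to floating-point error. Raw EDF channels
#' differ in physical scale by orders of magnitude (EEG microvolts versus the
#' aggregated EMG), and unnormalized fusion destabilizes training, so this is
#' applied by default in the pipeline commands.
#'
#' @param epochs a [SleepEpochSet-class].
#' @param eps guard against zero variance (default 1e-8).
#' @return the normalized [SleepEpochSet-class].
#' @export
normalizeEpochs <- function(epochs, eps = 1e-8) {
  sig <- epochs@signals
  d <- dim(sig)
  for (rec in unique(epochs@recordingId)) {
    e <- which(epochs@recordingId == rec)
    for (ch in seq_len(d[2])) {
      x <- sig[e, ch, ]
      mu <- mean(x)
      sdv <- stats::sd(as.vector(x))
      # sd() uses the n-1 denominator; for epoch sets n is large enough that
      # the distinction is immaterial, and idempotence holds either way
      sig[e, ch, ] <- (x - mu) / (sdv + eps)
    }
  }
  new("SleepEpochSet",
    signals = sig, labels = epochs@labels,
    subjectId = epochs@subjectId, recordingId = epochs@recordingId,
    channelOrder = epochs@channelOrder, samplingRate = epochs@samplingRate,
    epochSec = epochs@epochSec, normalized = TRUE
  )
}

#' Combine several epoch sets into one
#' @param ... SleepEpochSet objects with identical channel order and epoch
#'   geometry.
#' @return a single [SleepEpochSet-class].
#' @export
bindEpochSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !methods::is(sets[[1]], "SleepEpochSet")) {
    sets <- sets[[1]]
  }
  ref <- sets[[1]]
  total <- sum(vapply(sets, nEpochs, integer(1)))
  d <- dim(ref@signals)
  sig <- array(0, dim = c(total, d[2], d[3]))
  labels <- integer(total)
  subj <- character(total)
  recs <- character(total)
  at <- 0L
  for (s in sets) {
    stopifnot(identical(s@channelOrder, ref@channelOrder),
      dim(s@signals)[3] == d[3])
    n <- nEpochs(s)
    if (n) {
      sig[(at + 1):(at + n), , ] <- s@signals
      labels[(at + 1):(at + n)] <- s@labels
      subj[(at + 1):(at + n)] <- s@subjectId
      recs[(at + 1):(at + n)] <- s@recordingId
      at <- at + n
    }
  }
  new("SleepEpochSet",
    signals = sig, labels = labels, subjectId = subj, recordingId = recs,
    channelOrder = ref@channelOrder, samplingRate = ref@samplingRate,
    epochSec = ref@epochSec, normalized = ref@normalized
  )
}

#' Per-class epoch counts of an epoch set
#' @param epochs a [SleepEpochSet-class].
#' @return named integer vector over the five stages.
#' @export
stageCounts <- function(epochs) {
  tab <- table(factor(epochLabels(epochs), levels = 0:4, labels = stageNames()))
  stats::setNames(as.integer(tab), names(tab))
}
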