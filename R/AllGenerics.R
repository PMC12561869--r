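# Generics and accessors.

#' @rdname SleepEpochSet-class
#' @param x object.
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname SleepEpochSet-class
#' @export
setGeneric("epochSignals", function(x) standardGeneric("epochSignals"))

#' @rdname SleepEpochSet-class
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))

#' @rdname SleepEpochSet-class
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname SleepEpochSet-class
#' @export
setGeneric("recordingIds", function(x) standardGeneric("recordingIds"))

#' @rdname TimeSeriesRecording-class
#' @param x object.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname TimeSeriesRecording-class
#' @export
setGeneric("samplingRates", function(x) standardGeneric("samplingRates"))

#' @rdname AnnotationTrack-class
#' @param x object.
#' @export
setGeneric("annotationEvents", function(x) standardGeneric("annotationEvents"))

#' @rdname ConfusionMatrix-class
#' @param x object.
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname FoldPlan-class
#' @param x object.
#' @export
setGeneric("foldAssignments", function(x) standardGeneric("foldAssignments"))

#' @rdname SleepNetModel-class
#' @param x object.
#' @export
setGeneric("variantName", function(x) standardGeneric("variantName"))

#' @rdname SleepNetModel-class
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname SleepNetModel-class
#' @export
setGeneric("nParameters", function(x) standardGeneric("nParameters"))

setMethod("nEpochs", "SleepEpochSet", function(x) dim(x@signals)[1])
setMethod("epochSignals", "SleepEpochSet", function(x) x@signals)
setMethod("epochLabels", "SleepEpochSet", function(x) x@labels)
setMethod("subjectIds", "SleepEpochSet", function(x) x@subjectId)
setMethod("recordingIds", "SleepEpochSet", function(x) x@recordingId)

setMethod("channelLabels", "TimeSeriesRecording", function(x) names(x@signals))
setMethod("samplingRates", "TimeSeriesRecording", function(x) x@samplingRates)
setMethod("channelLabels", "SleepEpochSet", function(x) x@channelOrder)

setMethod("annotationEvents", "AnnotationTrack", function(x) x@events)

setMethod("counts", "ConfusionMatrix", function(x) x@counts)

setMethod("foldAssignments", "FoldPlan", function(x) x@folds)

setMethod("variantName", "SleepNetModel", function(x) x@variant)
setMethod("modelConfig", "SleepNetModel", function(x) x@config)
setMethod("nParameters", "SleepNetModel", function(x) {
  sum(vapply(x@params, length, integer(1)))
})

#' Subset a SleepEpochSet by epoch index
#'
#' @param x a SleepEpochSet.
#' @param i integer or logical index over epochs.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "SleepEpochSet", function(x, i, j, ..., drop = FALSE) {
  new("SleepEpochSet",
    signals = x@signals[i, , , drop = FALSE],
    labels = x@labels[i],
    subjectId = x@subjectId[i],
    recordingId = x@recordingId[i],
    channelOrder = x@channelOrder,
    samplingRate = x@samplingRate,
    epochSec = x@epochSec,
    normalized = x@normalized
  )
})

setMethod("show", "TimeSeriesRecording", function(object) {
  cat(sprintf(
    "TimeSeriesRecording '%s' (subject %s)\n",
    object@recordingId, object@subjectId
  ))
  for (lab in names(object@signals)) {
    cat(sprintf(
      "  %-16s %8d samples @ %g Hz\n", lab,
      length(object@signals[[lab]]), object@samplingRates[[lab]]
    ))
  }
})

setMethod("show", "AnnotationTrack", function(object) {
  ev <- object@events
  cat(sprintf("AnnotationTrack with %d events\n", nrow(ev)))
  if (nrow(ev)) {
    cat(sprintf(
      "  span: %g .. %g s\n", ev$onset[1],
      ev$onset[nrow(ev)] + ev$duration[nrow(ev)]
    ))
  }
})

setMethod("show", "SleepEpochSet", function(object) {
  d <- dim(object@signals)
  cat(sprintf(
    "SleepEpochSet: %d epochs x %d channels x %d samples (%s)\n",
    d[1], d[2], d[3],
    if (object@normalized) "normalized" else "raw"
  ))
  cat(sprintf("  subjects: %d\n", length(unique(object@subjectId))))
  if (d[1]) {
    tab <- table(factor(object@labels, levels = 0:4, labels = stageNames()))
    cat("  stages: ", paste(names(tab), as.integer(tab),
      sep = "=", collapse = " "
    ), "\n")
  }
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = truth, cols = predicted)\n")
  print(object@counts)
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d folds (seed %d)\n", object@k, object@seed))
  for (i in seq_along(object@folds)) {
    f <- object@folds[[i]]
    cat(sprintf(
      "  fold %d: %d train / %d test subjects\n",
      i, length(f$train), length(f$test)
    ))
  }
})

setMethod("show", "SleepNetModel", function(object) {
  cat(sprintf(
    "SleepNetModel variant '%s'%s, %d parameters\n",
    object@variant, if (object@trained) " (trained)" else "",
    nParameters(object)
  ))
})
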