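# Evaluation: confusion matrix, one-vs-rest reduction, accuracy / macro-F1 /
# Cohen's kappa / sensitivity / specificity / precision, hypnogram traces.

#' Build a 5x5 confusion matrix from stage labels
#'
#' @param truth,predicted integer stage codes in 0..4, equal length.
#' @return a [ConfusionMatrix-class]; `counts(x)[i, j]` is the number of
#'   epochs with true stage `i-1` predicted as stage `j-1`.
#' @export
confusionMatrix <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stopf(
      "truth (%d) and predicted (%d) must have equal length",
      length(truth), length(predicted)
    )
  }
  if (length(truth) && (min(c(truth, predicted)) < 0 ||
    max(c(truth, predicted)) > 4)) {
    stopf("labels must be stage codes in 0..4")
  }
  cm <- table(
    factor(truth, levels = 0:4),
    factor(predicted, levels = 0:4)
  )
  cm <- matrix(as.numeric(cm), 5, 5,
    dimnames = list(truth = stageNames(), predicted = stageNames())
  )
  new("ConfusionMatrix", counts = cm)
}

#' One-vs-rest reduction of a confusion matrix
#'
#' Reduces the 5-class matrix to binary counts for one stage: epochs of that
#' stage are positives, all others negatives.
#'
#' @param conf a [ConfusionMatrix-class].
#' @param k stage code in 0..4.
#' @return named numeric vector with `TP`, `FP`, `TN`, `FN`.
#' @export
oneVsRest <- function(conf, k) {
  stopifnot(k %in% 0:4)
  cm <- counts(conf)
  i <- k + 1L
  tp <- cm[i, i]
  fp <- sum(cm[, i]) - tp
  fn <- sum(cm[i, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

.safeRatio <- function(num, den, what, stage) {
  if (den == 0) {
    warnf("%s undefined for stage %s (empty denominator); reporting 0",
      what, stage)
    return(0)
  }
  num / den
}

#' Compute the full evaluation report from a confusion matrix
#'
#' Overall accuracy is the trace over the total. Per stage, one-vs-rest
#' counts give sensitivity TP/(TP+FN), specificity TN/(TN+FP) and precision
#' TP/(TP+FP); per-stage F1 is the harmonic mean 2*PRE*SEN/(PRE+SEN). The
#' macro scores are unweighted means over the five stages. Cohen's kappa is
#' (P0 - Pe)/(1 - Pe) with P0 the observed accuracy and Pe the expected
#' agreement of independent marginals, `sum(row_k * col_k) / total^2`.
#' Ratios with an empty denominator (a stage absent from both truth and
#' prediction) are reported as 0 with a warning so pooled cross-fold reports
#' never fail.
#'
#' @param conf a [ConfusionMatrix-class] with at least one count.
#' @return a list with elements `ACC`, `F1_Macro`, `Kappa`, `SEN`, `SPE`,
#'   `PRE` (macro averages) and `perClass`, a data.frame with one row per
#'   stage and columns `PRE`, `SEN`, `SPE`, `F1`. All values are proportions
#'   in `[0, 1]` (kappa in `[-1, 1]`).
#' @export
computeMetrics <- function(conf) {
  cm <- counts(conf)
  total <- sum(cm)
  if (total == 0) stopf("empty confusion matrix")
  acc <- sum(diag(cm)) / total

  per <- data.frame(
    stage = stageNames(), PRE = NA_real_, SEN = NA_real_,
    SPE = NA_real_, F1 = NA_real_
  )
  for (k in 0:4) {
    b <- oneVsRest(conf, k)
    pre <- .safeRatio(b["TP"], b["TP"] + b["FP"], "precision", stageNames()[k + 1])
    sen <- .safeRatio(b["TP"], b["TP"] + b["FN"], "sensitivity", stageNames()[k + 1])
    spe <- .safeRatio(b["TN"], b["TN"] + b["FP"], "specificity", stageNames()[k + 1])
    f1 <- if (pre + sen == 0) 0 else 2 * pre * sen / (pre + sen)
    per[k + 1L, 2:5] <- c(pre, sen, spe, f1)
  }

  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (pe == 1) 0 else (acc - pe) / (1 - pe)

  list(
    ACC = acc,
    F1_Macro = mean(per$F1),
    Kappa = kappa,
    SEN = mean(per$SEN),
    SPE = mean(per$SPE),
    PRE = mean(per$PRE),
    perClass = per
  )
}

#' Stage-vs-time traces for hypnogram plots
#'
#' Maps true and predicted stage codes onto the conventional hypnogram
#' ordinate (top to bottom: W, REM, N1, N2, N3) so both traces can be drawn
#' as step functions over the epoch index.
#'
#' @param labels,predictions integer stage codes, equal length.
#' @return a data.frame with columns `epoch`, `truth`, `predicted` (ordinate
#'   levels) plus attribute `"levels"` giving the ordinate-to-stage mapping.
#' @export
hypnogramSeries <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stopf("labels and predictions must have equal length")
  }
  # ordinate level per stage code 0:4 (W, N1, N2, N3, REM)
  ord <- c(5L, 3L, 2L, 1L, 4L)
  out <- data.frame(
    epoch = seq_along(labels),
    truth = ord[labels + 1L],
    predicted = ord[predictions + 1L]
  )
  attr(out, "levels") <- c(N3 = 1L, N2 = 2L, N1 = 3L, REM = 4L, W = 5L)
  out
}

#' Invert hypnogram ordinate levels back to stage codes
#' @param levels integer ordinate levels as produced by [hypnogramSeries()].
#' @return integer stage codes in 0..4.
#' @export
hypnogramLevelsToStages <- function(levels) {
  inv <- integer(5)
  inv[c(5L, 3L, 2L, 1L, 4L)] <- 0:4
  inv[levels]
}

#' Write a metrics report as flat text and a per-class table
#'
#' @param metrics result of [computeMetrics()].
#' @param conf the [ConfusionMatrix-class] it came from.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
writeMetricsReport <- function(metrics, conf, dir, prefix = "metrics") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- file.path(dir, paste0(prefix, ".txt"))
  overall <- unlist(metrics[c("ACC", "F1_Macro", "Kappa", "SEN", "SPE", "PRE")])
  writeLines(sprintf("%s\t%.6f", names(overall), overall), flat)
  tab <- file.path(dir, paste0(prefix, "_per_class.tsv"))
  per <- metrics$perClass
  macro <- data.frame(
    stage = "macro", PRE = metrics$PRE, SEN = metrics$SEN,
    SPE = metrics$SPE, F1 = metrics$F1_Macro
  )
  utils::write.table(rbind(per, macro), tab,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  cmPath <- file.path(dir, paste0(prefix, "_confusion.csv"))
  utils::write.csv(counts(conf), cmPath)
  invisible(c(flat, tab, cmPath))
}
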