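# EDF / EDF+ input and output.
#
# Implements the 16-bit EDF format (256-byte fixed header, 256 bytes per
# signal header, little-endian int16 data records) plus the EDF+ annotation
# channel ("EDF Annotations", time-stamped annotation lists) in the dialect
# used by expanded sleep-cassette hypnogram files. Only continuous (EDF+C)
# files are supported.

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stopf("EDF header field too long: '%s'", x)
  formatC(x, width = width, flag = "-")
}

# Serialize a number into an EDF ASCII field of the given width; reduces
# significant digits until it fits.
.edfNumStr <- function(x, width) {
  for (d in 10:1) {
    s <- formatC(signif(x, d), format = "fg")
    if (nchar(s) <= width) return(s)
  }
  stopf("cannot represent %g in %d EDF header bytes", x, width)
}

.edfNum <- function(x, width) .edfPad(.edfNumStr(x, width), width)

.readField <- function(raw, offset, width) {
  trimws(rawToChar(raw[(offset + 1):(offset + width)]))
}

# Parse the full EDF header. Returns a list with global fields and a
# data.frame of per-signal fields.
.readEDFHeader <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readBin(con, "raw", 256)
  if (length(fixed) < 256) {
    stopf("corrupt EDF header in '%s': file shorter than 256 bytes", path)
  }
  version <- .readField(fixed, 0, 8)
  if (version != "0") {
    stopf(
      "corrupt EDF header in '%s': version field at byte offset 0 is '%s', expected '0'",
      path, version
    )
  }
  ns <- suppressWarnings(as.integer(.readField(fixed, 252, 4)))
  if (is.na(ns) || ns < 1) {
    stopf("corrupt EDF header in '%s': signal count at byte offset 252 unreadable", path)
  }
  headerBytes <- suppressWarnings(as.integer(.readField(fixed, 184, 8)))
  if (is.na(headerBytes) || headerBytes != 256 * (ns + 1)) {
    stopf(
      "corrupt EDF header in '%s': header size at byte offset 184 (%s) != 256*(ns+1)",
      path, .readField(fixed, 184, 8)
    )
  }
  nRecords <- suppressWarnings(as.integer(.readField(fixed, 236, 8)))
  recordSec <- suppressWarnings(as.numeric(.readField(fixed, 244, 8)))
  if (is.na(nRecords) || is.na(recordSec)) {
    stopf("corrupt EDF header in '%s': record fields at byte offset 236 unreadable", path)
  }

  sig <- readBin(con, "raw", 256 * ns)
  fieldWidths <- c(
    label = 16, transducer = 80, physDim = 8, physMin = 8, physMax = 8,
    digMin = 8, digMax = 8, prefilter = 80, samplesPerRecord = 8, reserved = 32
  )
  sigTab <- list()
  offset <- 0
  for (fn in names(fieldWidths)) {
    w <- fieldWidths[[fn]]
    vals <- vapply(seq_len(ns), function(i) {
      .readField(sig, offset + (i - 1) * w, w)
    }, character(1))
    sigTab[[fn]] <- vals
    offset <- offset + ns * w
  }
  sigTab <- as.data.frame(sigTab, stringsAsFactors = FALSE)
  for (fn in c("physMin", "physMax", "digMin", "digMax", "samplesPerRecord")) {
    sigTab[[fn]] <- as.numeric(sigTab[[fn]])
  }
  list(
    patient = .readField(fixed, 8, 80),
    recording = .readField(fixed, 88, 80),
    reserved = .readField(fixed, 192, 44),
    nRecords = nRecords, recordSec = recordSec, ns = ns,
    headerBytes = headerBytes, signals = sigTab
  )
}

# Read the raw data records; returns a list with one element per signal:
# for ordinary signals an integer vector, for annotation signals raw bytes.
.readEDFData <- function(path, hdr) {
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, hdr$headerBytes)
  spr <- hdr$signals$samplesPerRecord
  isAnnot <- hdr$signals$label == "EDF Annotations"
  out <- vector("list", hdr$ns)
  for (i in seq_len(hdr$ns)) {
    out[[i]] <- if (isAnnot[i]) raw(0) else integer(hdr$nRecords * spr[i])
  }
  for (r in seq_len(hdr$nRecords)) {
    for (i in seq_len(hdr$ns)) {
      if (isAnnot[i]) {
        out[[i]] <- c(out[[i]], readBin(con, "raw", 2 * spr[i]))
      } else {
        idx <- ((r - 1) * spr[i] + 1):(r * spr[i])
        out[[i]][idx] <- readBin(con, "integer",
          n = spr[i], size = 2, signed = TRUE, endian = "little"
        )
      }
    }
  }
  out
}

#' Linear-interpolation resampling
#'
#' Resamples a uniformly sampled signal to a new rate by linear
#' interpolation, preserving duration: the output length is
#' `round(length(x) * rateOut / rateIn)`.
#'
#' @param x numeric vector.
#' @param rateIn,rateOut sampling rates in Hz.
#' @return numeric vector at `rateOut`.
#' @export
linearResample <- function(x, rateIn, rateOut) {
  if (rateIn == rateOut) {
    return(x)
  }
  nOut <- round(length(x) * rateOut / rateIn)
  tIn <- (seq_along(x) - 1) / rateIn
  tOut <- (seq_len(nOut) - 1) / rateOut
  stats::approx(tIn, x, xout = tOut, rule = 2)$y
}

#' Read polysomnography signals from an EDF/EDF+ file
#'
#' Reads the channels matching `channelSpec`, applies the digital-to-physical
#' calibration declared in the signal headers, and resamples every retained
#' channel to a common rate (linear interpolation; the public sleep-cassette
#' files store the submental EMG at 1 Hz while the model consumes 100 Hz).
#' Matching is case-insensitive substring matching, so the default spec
#' matches the "EEG Fpz-Cz", "EEG Pz-Oz", "EOG horizontal" and
#' "EMG submental" labels of the sleep-cassette montage. Event-marker and
#' other unmatched channels are ignored.
#'
#' @param path EDF file path.
#' @param channelSpec character vector of channel-label patterns, one
#'   retained channel per pattern (first match wins).
#' @param targetRate common sampling rate in Hz (default 100).
#' @param subjectId,recordingId identifiers; default to the EDF patient
#'   field's first token and the file name.
#' @return a [TimeSeriesRecording-class].
#' @export
readPSG <- function(path, channelSpec = channelOrder(), targetRate = 100,
                    subjectId = NULL, recordingId = NULL) {
  if (!file.exists(path)) stopf("no such file: '%s'", path)
  hdr <- .readEDFHeader(path)
  data <- .readEDFData(path, hdr)
  labels <- hdr$signals$label
  signals <- list()
  rates <- numeric()
  for (pat in channelSpec) {
    hit <- which(grepl(tolower(pat), tolower(labels), fixed = TRUE) &
      labels != "EDF Annotations")
    if (!length(hit)) {
      stopf(
        "channel pattern '%s' matched no channel in '%s' (available: %s)",
        pat, path, paste(setdiff(labels, "EDF Annotations"), collapse = ", ")
      )
    }
    i <- hit[1]
    s <- hdr$signals[i, ]
    gain <- (s$physMax - s$physMin) / (s$digMax - s$digMin)
    phys <- (data[[i]] - s$digMin) * gain + s$physMin
    rate <- s$samplesPerRecord / hdr$recordSec
    signals[[labels[i]]] <- linearResample(phys, rate, targetRate)
    rates[labels[i]] <- targetRate
  }
  pat <- strsplit(hdr$patient, " +")[[1]]
  TimeSeriesRecording(
    recordingId = recordingId %||% sub("\\.edf$", "", basename(path),
      ignore.case = TRUE
    ),
    subjectId = subjectId %||% (if (length(pat)) pat[1] else "unknown"),
    signals = signals, samplingRates = rates
  )
}

# Split concatenated annotation bytes into (onset, duration, label) events.
# TALs are nul-terminated, so the split happens at the raw-byte level (R
# strings cannot carry embedded nuls).
.parseTALs <- function(bytes) {
  boundaries <- c(0L, which(bytes == as.raw(0)))
  txt <- character(0)
  for (i in seq_len(length(boundaries) - 1L)) {
    lo <- boundaries[i] + 1L
    hi <- boundaries[i + 1L] - 1L
    if (hi >= lo) txt <- c(txt, rawToChar(bytes[lo:hi]))
  }
  onset <- numeric()
  duration <- numeric()
  label <- character()
  for (tal in txt) {
    if (!nzchar(tal)) next
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    head <- parts[1]
    anns <- parts[-1]
    anns <- anns[nzchar(anns)]
    if (!length(anns)) next # bare time-keeping TAL
    hp <- strsplit(head, "\x15", fixed = TRUE)[[1]]
    on <- as.numeric(hp[1])
    du <- if (length(hp) > 1) as.numeric(hp[2]) else 0
    if (is.na(on)) next
    if (is.na(du) || du <= 0) next # zero-duration bookkeeping annotation
    for (a in anns) {
      onset <- c(onset, on)
      duration <- c(duration, du)
      label <- c(label, a)
    }
  }
  data.frame(onset = onset, duration = duration, label = label,
    stringsAsFactors = FALSE)
}

#' Read a hypnogram from an EDF+ annotation file
#'
#' Every scored interval in the "EDF Annotations" signal becomes one event;
#' zero-duration bookkeeping annotations and bare time-keeping stamps are
#' dropped. Durations that are not multiples of 30 s are retained with a
#' warning (they do not conform to the 30 s scoring grid).
#'
#' @param path EDF+ file path.
#' @return an [AnnotationTrack-class].
#' @export
readHypnogram <- function(path) {
  if (!file.exists(path)) stopf("no such file: '%s'", path)
  hdr <- .readEDFHeader(path)
  ai <- which(hdr$signals$label == "EDF Annotations")
  if (!length(ai)) {
    stopf("'%s' has no EDF Annotations signal; not an EDF+ annotation file", path)
  }
  data <- .readEDFData(path, hdr)
  ev <- .parseTALs(data[[ai[1]]])
  ev <- ev[order(ev$onset), , drop = FALSE]
  bad <- ev$duration %% 30 != 0
  if (any(bad)) {
    warnf(
      "%d annotation(s) with duration not a multiple of 30 s retained (e.g. %gs '%s')",
      sum(bad), ev$duration[which(bad)[1]], ev$label[which(bad)[1]]
    )
  }
  AnnotationTrack(ev$onset, ev$duration, ev$label)
}

# One time-stamped annotation list as raw bytes (incl. the nul terminator).
.buildTAL <- function(onset, duration = NULL, labels = character()) {
  head <- sprintf("%+g", onset)
  if (!is.null(duration)) head <- paste0(head, "\x15", sprintf("%g", duration))
  s <- paste0(head, "\x14", paste0(labels, "\x14", collapse = ""),
    if (!length(labels)) "\x14" else "")
  c(charToRaw(s), as.raw(0))
}

#' Write an EDF/EDF+ file
#'
#' Writes the recording's channels as 16-bit EDF signals, optionally with an
#' EDF+ annotation channel carrying the hypnogram events. The written file
#' round-trips through [readPSG()]/[readHypnogram()]: labels, rates and
#' annotation triples exactly, sample values within the 16-bit quantization
#' step of the declared physical range.
#'
#' @param recording a [TimeSeriesRecording-class], or `NULL` for an
#'   annotation-only EDF+ file.
#' @param path output path.
#' @param annotations optional [AnnotationTrack-class].
#' @param physicalRange optional named numeric vector of symmetric physical
#'   ranges per channel (uV); amplitudes beyond the declared range are an
#'   error. Default: a small margin above each channel's observed maximum.
#' @param recordSec data-record duration in seconds (default 1).
#' @return the path, invisibly.
#' @export
writeEDF <- function(recording, path, annotations = NULL,
                     physicalRange = NULL, recordSec = 1) {
  signals <- if (is.null(recording)) list() else recording@signals
  rates <- if (is.null(recording)) numeric() else recording@samplingRates
  nSig <- length(signals)

  if (nSig) {
    durations <- vapply(seq_len(nSig), function(i) {
      length(signals[[i]]) / rates[[i]]
    }, numeric(1))
    if (length(unique(round(durations, 9))) != 1L) {
      stopf("all channels must span the same duration")
    }
    nRecords <- ceiling(durations[1] / recordSec)
  } else {
    nRecords <- 1L
  }

  # digital scaling per channel; symmetric digital range so physical zero
  # digitizes exactly to zero
  digMin <- -32767
  digMax <- 32767
  ranges <- numeric(nSig)
  for (i in seq_len(nSig)) {
    lab <- names(signals)[i]
    obs <- max(abs(signals[[i]]))
    r <- if (!is.null(physicalRange) && lab %in% names(physicalRange)) {
      physicalRange[[lab]]
    } else {
      max(obs * 1.01, 1) # at least 1 uV so the header stays representable
    }
    if (obs > r) {
      stopf(
        "channel '%s' amplitude %.3f uV exceeds declared physical range %.3f uV",
        lab, obs, r
      )
    }
    # digitize against the range exactly as serialized in the header, so the
    # reader's calibration inverts the writer's
    r2 <- as.numeric(.edfNumStr(r, 7))
    while (r2 < obs) {
      r <- r * 1.1
      r2 <- as.numeric(.edfNumStr(r, 7))
    }
    ranges[i] <- r2
  }

  # annotation payload: time-stamp TAL per record, all events in record 1
  hasAnnot <- !is.null(annotations)
  annotPerRecord <- NULL
  if (hasAnnot || is.null(recording)) {
    hasAnnot <- TRUE
    ev <- if (is.null(annotations)) {
      data.frame(onset = numeric(), duration = numeric(), label = character())
    } else {
      annotationEvents(annotations)
    }
    annotBytes <- vector("list", nRecords)
    for (r in seq_len(nRecords)) {
      annotBytes[[r]] <- .buildTAL((r - 1) * recordSec)
    }
    for (j in seq_len(nrow(ev))) {
      annotBytes[[1]] <- c(
        annotBytes[[1]],
        .buildTAL(ev$onset[j], ev$duration[j], ev$label[j])
      )
    }
    annotSpr <- ceiling(max(vapply(annotBytes, length, integer(1))) / 2)
    annotPerRecord <- lapply(annotBytes, function(b) {
      c(b, raw(2 * annotSpr - length(b)))
    })
  }

  ns <- nSig + as.integer(hasAnnot)
  con <- file(path, "wb")
  on.exit(close(con))

  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(.edfPad("0", 8))
  wr(.edfPad(
    if (is.null(recording)) "X" else paste(recording@subjectId, "F X X"), 80
  ))
  wr(.edfPad(
    if (is.null(recording)) "Startdate 01-JAN-2000" else {
      paste("Startdate 01-JAN-2000", recording@recordingId)
    }, 80
  ))
  wr(.edfPad("01.01.00", 8))
  wr(.edfPad("00.00.00", 8))
  wr(.edfNum(256 * (ns + 1), 8))
  wr(.edfPad(if (hasAnnot) "EDF+C" else "", 44))
  wr(.edfNum(nRecords, 8))
  wr(.edfNum(recordSec, 8))
  wr(.edfNum(ns, 4))

  labs <- c(names(signals), if (hasAnnot) "EDF Annotations")
  sprs <- c(
    vapply(seq_len(nSig), function(i) rates[[i]] * recordSec, numeric(1)),
    if (hasAnnot) annotSpr
  )
  if (any(sprs != round(sprs))) {
    stopf("sampling rate times record duration must be an integer")
  }
  physMins <- c(-ranges, if (hasAnnot) -1)
  physMaxs <- c(ranges, if (hasAnnot) 1)
  digMins <- c(rep(digMin, nSig), if (hasAnnot) digMin)
  digMaxs <- c(rep(digMax, nSig), if (hasAnnot) digMax)

  for (v in labs) wr(.edfPad(v, 16))
  for (v in labs) wr(.edfPad("", 80))
  for (i in seq_len(ns)) wr(.edfPad(if (i <= nSig) "uV" else "", 8))
  for (v in physMins) wr(.edfNum(v, 8))
  for (v in physMaxs) wr(.edfNum(v, 8))
  for (v in digMins) wr(.edfNum(v, 8))
  for (v in digMaxs) wr(.edfNum(v, 8))
  for (v in labs) wr(.edfPad("", 80))
  for (v in sprs) wr(.edfNum(v, 8))
  for (v in labs) wr(.edfPad("", 32))

  # digitize signals once, pad the tail record with zeros
  digital <- vector("list", nSig)
  for (i in seq_len(nSig)) {
    x <- signals[[i]]
    need <- nRecords * sprs[i]
    if (length(x) < need) x <- c(x, numeric(need - length(x)))
    g <- (2 * ranges[i]) / (digMax - digMin)
    digital[[i]] <- as.integer(round((x + ranges[i]) / g + digMin))
  }

  for (r in seq_len(nRecords)) {
    for (i in seq_len(nSig)) {
      idx <- ((r - 1) * sprs[i] + 1):(r * sprs[i])
      writeBin(digital[[i]][idx], con, size = 2, endian = "little")
    }
    if (hasAnnot) writeBin(annotPerRecord[[r]], con)
  }
  invisible(path)
}
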