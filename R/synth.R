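# Synthetic polysomnography: Markov-chain hypnograms plus stage-conditional
# 4-channel signals carrying the band-power and transient cues that
# distinguish sleep stages (alpha-dominant wake, spindling N2, delta-dominant
# N3, rapid EOG deflections with muscle atonia in REM). The point is not
# physiological realism but a download-free data source whose classes are
# provably learnable, so end-to-end failures implicate the model, not the
# data.

#' Stage-conditional signal model
#'
#' Parameters of the per-stage signal synthesis used by [synthesizeEpoch()].
#' Each stage combines narrowband EEG oscillations (random-phase sinusoids
#' with amplitude envelopes), stage-specific transients (12-14 Hz spindle
#' bursts and biphasic K-complex-like pulses in N2, rapid EOG deflections in
#' REM, slow rolling EOG in N1, blinks in W), a white-noise EMG whose RMS
#' encodes muscle tone (atonia in REM), and 1/f background noise on every
#' channel. Default EMG tone ordering: W > N1 >= N2 >= N3 > REM.
#'
#' Amplitudes are in arbitrary microvolt-like units.
#'
#' @param remEEGDistinct if `FALSE`, REM uses wake's EEG oscillation
#'   parameters, confining the REM/W cue to the EOG and EMG channels (used
#'   to probe sensitivity of architecture variants to non-EEG modalities).
#' @return a list of per-stage parameter lists, class `"StageSignalModel"`.
#' @export
stageSignalModel <- function(remEEGDistinct = TRUE) {
  m <- list(
    W = list(
      eeg = list(list(band = c(8, 12), amp = 30, type = "continuous")),
      eogOsc = list(),
      eogEvents = list(kind = "blink", n = 3, amp = 60, dur = 0.4),
      emgRMS = 10, bg = 10
    ),
    N1 = list(
      eeg = list(list(band = c(4, 7), amp = 20, type = "continuous")),
      eogOsc = list(list(band = c(0.25, 0.5), amp = 40, type = "continuous")),
      eogEvents = NULL,
      emgRMS = 6, bg = 10
    ),
    N2 = list(
      eeg = list(
        list(band = c(4, 7), amp = 12, type = "continuous"),
        list(band = c(12, 14), amp = 35, type = "burst", n = 4, dur = 0.8),
        list(band = c(0.7, 0.9), amp = 60, type = "burst", n = 2, dur = 1.2)
      ),
      eogOsc = list(),
      eogEvents = NULL,
      emgRMS = 5, bg = 12
    ),
    N3 = list(
      eeg = list(list(band = c(0.6, 1.8), amp = 80, type = "continuous")),
      eogOsc = list(),
      eogEvents = NULL,
      emgRMS = 4, bg = 12
    ),
    REM = list(
      eeg = list(list(band = c(4, 8), amp = 15, type = "continuous")),
      eogOsc = list(),
      eogEvents = list(kind = "rem", n = 6, amp = 70, dur = 0.5),
      emgRMS = 1.5, bg = 12
    )
  )
  if (!remEEGDistinct) {
    m$REM$eeg <- m$W$eeg
    m$REM$bg <- m$W$bg
  }
  structure(m, class = "StageSignalModel")
}

#' Markov hypnogram model
#'
#' Default transition matrix: stay in the current stage with probability
#' `persistence`, otherwise draw the next stage from the target stationary
#' distribution, i.e. `P = a*I + (1-a) * 1 %*% t(pi)`. This yields strong
#' self-transitions (diagonal ~0.87-0.92, mimicking sleep-stage persistence)
#' and has `pi` as its exact stationary distribution. The default `pi` is the
#' count-derived class balance of a public sleep-cassette archive
#' (W/N1/N2/N3/REM = 19.6/6.6/42.1/13.5/18.2%), so N1 is the rarest class.
#'
#' @param transition optional 5x5 row-stochastic matrix.
#' @param initial optional length-5 initial distribution (default: the
#'   stationary distribution of `transition`).
#' @param nEpochs number of 30 s epochs to simulate.
#' @param persistence self-transition weight `a` for the default matrix.
#' @param stationary target stationary distribution for the default matrix.
#' @return a list with `transition`, `initial`, `nEpochs`, class
#'   `"HypnogramModel"`.
#' @export
hypnogramModel <- function(transition = NULL, initial = NULL, nEpochs = 1000,
                           persistence = 0.86,
                           stationary = c(0.196, 0.066, 0.421, 0.135, 0.182)) {
  if (is.null(transition)) {
    stationary <- stationary / sum(stationary)
    transition <- persistence * diag(5) +
      (1 - persistence) * matrix(stationary, 5, 5, byrow = TRUE)
  }
  if (!all(dim(transition) == c(5, 5)) || any(transition < 0) ||
    any(abs(rowSums(transition) - 1) > 1e-9)) {
    stopf("transition must be a 5x5 row-stochastic matrix (rows sum to 1)")
  }
  if (is.null(initial)) initial <- stationaryDistribution(transition)
  if (length(initial) != 5 || any(initial < 0) ||
    abs(sum(initial) - 1) > 1e-9) {
    stopf("initial must be a length-5 probability vector")
  }
  dimnames(transition) <- list(stageNames(), stageNames())
  structure(list(
    transition = transition, initial = as.numeric(initial),
    nEpochs = as.integer(nEpochs)
  ), class = "HypnogramModel")
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of eigenvalue 1, normalized to sum 1.
#'
#' @param P row-stochastic matrix.
#' @return numeric probability vector.
#' @export
stationaryDistribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Simulate a hypnogram from a Markov model
#'
#' @param model a [hypnogramModel()].
#' @param seed optional integer seed (reproducible sequences).
#' @return integer vector of stage codes, length `model$nEpochs`.
#' @export
simulateHypnogram <- function(model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- model$nEpochs
  out <- integer(n)
  s <- sample.int(5, 1, prob = model$initial)
  out[1] <- s - 1L
  for (i in seq_len(n - 1L)) {
    s <- sample.int(5, 1, prob = model$transition[s, ])
    out[i + 1L] <- s - 1L
  }
  out
}

# 1/f^beta Gaussian background, band-limited below by floorHz, scaled to a
# target RMS.
.onefNoise <- function(n, scale, beta = 1, floorHz = 0.5, rate = 100) {
  nf <- n %/% 2 - 1L
  f <- (1:nf) * rate / n
  amp <- pmax(f, floorHz)^(-beta / 2)
  coefs <- complex(
    real = stats::rnorm(nf) * amp,
    imaginary = stats::rnorm(nf) * amp
  )
  spec <- complex(real = numeric(n), imaginary = numeric(n))
  spec[2:(nf + 1)] <- coefs
  spec[n:(n - nf + 1)] <- Conj(coefs)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x * scale / max(stats::sd(x), 1e-12)
}

# Narrowband oscillation: continuous tone with a slow random amplitude
# envelope, or a number of Hann-windowed bursts at random positions.
.oscillation <- function(n, rate, band, amp, type = "continuous",
                         nBursts = 0, burstDur = 1) {
  t <- (seq_len(n) - 1) / rate
  f0 <- stats::runif(1, band[1], band[2])
  carrier <- sin(2 * pi * f0 * t + stats::runif(1, 0, 2 * pi))
  if (type == "continuous") {
    env <- 1 + 0.3 * sin(2 * pi * stats::runif(1, 0.05, 0.15) * t +
      stats::runif(1, 0, 2 * pi))
    return(amp * env * carrier)
  }
  x <- numeric(n)
  len <- max(8L, round(burstDur * rate))
  win <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = len)))
  for (b in seq_len(nBursts)) {
    at <- sample.int(n - len, 1)
    x[at:(at + len - 1L)] <- x[at:(at + len - 1L)] + amp * win *
      carrier[at:(at + len - 1L)]
  }
  x
}

# Transient EOG events: blinks (monophasic pulses) or rapid-eye-movement
# deflections (sharp biphasic ramps with alternating sign).
.eogEvents <- function(n, rate, kind, nEvents, amp, dur) {
  x <- numeric(n)
  len <- max(8L, round(dur * rate))
  shape <- if (kind == "blink") {
    0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = len)))
  } else {
    sin(2 * pi * seq(0, 1, length.out = len)) *
      exp(-3 * seq(0, 1, length.out = len))
  }
  sign <- 1
  for (b in seq_len(nEvents)) {
    at <- sample.int(n - len, 1)
    x[at:(at + len - 1L)] <- x[at:(at + len - 1L)] + sign * amp * shape
    sign <- -sign
  }
  x
}

#' Synthesize one 30 s epoch of 4-channel PSG for a given stage
#'
#' Draws from the current RNG state; seed externally (or via the dataset
#' builder) for reproducibility.
#'
#' @param stage integer stage code in 0..4.
#' @param model a [stageSignalModel()].
#' @param rate sampling rate in Hz.
#' @param epochSec epoch length in seconds.
#' @return numeric matrix (4 channels x samples) with [channelOrder()] rows.
#' @export
synthesizeEpoch <- function(stage, model = stageSignalModel(), rate = 100,
                            epochSec = 30) {
  stopifnot(stage %in% 0:4)
  p <- model[[stage + 1L]]
  n <- as.integer(rate * epochSec)
  x <- matrix(0, 4, n, dimnames = list(channelOrder(), NULL))
  for (ch in 1:2) {
    eeg <- .onefNoise(n, p$bg, rate = rate)
    for (o in p$eeg) {
      eeg <- eeg + .oscillation(n, rate, o$band, o$amp * stats::runif(1, 0.8, 1.2),
        o$type, o$n %||% 0, o$dur %||% 1
      )
    }
    x[ch, ] <- eeg
  }
  eog <- .onefNoise(n, p$bg * 0.8, rate = rate)
  for (o in p$eogOsc) {
    eog <- eog + .oscillation(n, rate, o$band, o$amp * stats::runif(1, 0.8, 1.2),
      o$type %||% "continuous"
    )
  }
  if (!is.null(p$eogEvents)) {
    ev <- p$eogEvents
    eog <- eog + .eogEvents(n, rate, ev$kind, ev$n, ev$amp, ev$dur)
  }
  x[3, ] <- eog
  x[4, ] <- stats::rnorm(n, sd = p$emgRMS) + .onefNoise(n, 0.5, rate = rate)
  x
}

#' Generate a full synthetic multi-subject epoch dataset
#'
#' Simulates one hypnogram per subject from the Markov model and synthesizes
#' the corresponding stage-conditional epochs. Per-subject seeds are derived
#' deterministically from the master seed, so the dataset is bit-identical
#' across runs for a fixed seed. Optionally exports each subject as an EDF+
#' pair (signals + hypnogram annotations) so the EDF reading and epoching
#' path can be exercised end to end.
#'
#' @param nSubjects number of subjects (default 10).
#' @param epochsPerSubject epochs per subject (default 200).
#' @param hypModel a [hypnogramModel()]; its `nEpochs` is overridden by
#'   `epochsPerSubject`.
#' @param sigModel a [stageSignalModel()].
#' @param seed master seed.
#' @param rate,epochSec sampling geometry.
#' @param edfDir if non-NULL, write `<subject>-PSG.edf` and
#'   `<subject>-Hypnogram.edf` files there.
#' @return a raw (unnormalized) [SleepEpochSet-class].
#' @export
makeSyntheticDataset <- function(nSubjects = 10, epochsPerSubject = 200,
                                 hypModel = hypnogramModel(),
                                 sigModel = stageSignalModel(),
                                 seed = 1, rate = 100, epochSec = 30,
                                 edfDir = NULL) {
  stopifnot(nSubjects >= 1)
  n <- nSubjects * epochsPerSubject
  spe <- as.integer(rate * epochSec)
  sig <- array(0, dim = c(n, 4, spe))
  labels <- integer(n)
  subj <- character(n)
  hm <- hypnogramModel(
    transition = hypModel$transition, initial = hypModel$initial,
    nEpochs = epochsPerSubject
  )
  at <- 0L
  for (s in seq_len(nSubjects)) {
    sid <- sprintf("S%02d", s)
    set.seed(deriveSeed(seed, s))
    hyp <- simulateHypnogram(hm)
    for (e in seq_len(epochsPerSubject)) {
      sig[at + e, , ] <- synthesizeEpoch(hyp[e], sigModel, rate, epochSec)
    }
    labels[(at + 1):(at + epochsPerSubject)] <- hyp
    subj[(at + 1):(at + epochsPerSubject)] <- sid
    if (!is.null(edfDir)) {
      .exportSubjectEDF(sig[(at + 1):(at + epochsPerSubject), , , drop = FALSE],
        hyp, sid, edfDir, rate, epochSec)
    }
    at <- at + epochsPerSubject
  }
  SleepEpochSet(
    signals = sig, labels = labels, subjectId = subj, recordingId = subj,
    samplingRate = rate, epochSec = epochSec, normalized = FALSE
  )
}

.stageAnnotation <- c(
  "Sleep stage W", "Sleep stage 1", "Sleep stage 2",
  "Sleep stage 3", "Sleep stage R"
)

.exportSubjectEDF <- function(sig, hyp, sid, dir, rate, epochSec) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chans <- lapply(seq_len(dim(sig)[2]), function(ch) {
    as.vector(t(sig[, ch, ]))
  })
  names(chans) <- channelOrder()
  rec <- TimeSeriesRecording(sid, sid, chans, rate)
  writeEDF(rec, file.path(dir, paste0(sid, "-PSG.edf")))
  runs <- rle(hyp)
  ends <- cumsum(runs$lengths)
  onsets <- (ends - runs$lengths) * epochSec
  track <- AnnotationTrack(onsets, runs$lengths * epochSec,
    .stageAnnotation[runs$values + 1L])
  writeEDF(NULL, file.path(dir, paste0(sid, "-Hypnogram.edf")),
    annotations = track)
  invisible(NULL)
}

#' Per-epoch spectral band-power features
#'
#' Simple hand-crafted features used by the linear-separability sanity check:
#' log band powers (delta 0.5-4, theta 4-8, alpha 8-12, sigma 12-15, beta
#' 15-30 Hz) for each EEG channel, low (0.1-1 Hz) and mid (1-5 Hz) log band
#' power for EOG, and log RMS for EMG.
#'
#' @param epochs a [SleepEpochSet-class].
#' @return numeric feature matrix, one row per epoch.
#' @export
epochBandPowers <- function(epochs) {
  sig <- epochSignals(epochs)
  n <- dim(sig)[1]
  spe <- dim(sig)[3]
  rate <- epochs@samplingRate
  freqs <- (seq_len(spe %/% 2) - 0) * rate / spe
  eegBands <- list(c(0.5, 4), c(4, 8), c(8, 12), c(12, 15), c(15, 30))
  bandIdx <- lapply(eegBands, function(b) which(freqs >= b[1] & freqs < b[2]))
  eogIdx <- lapply(list(c(0.1, 1), c(1, 5)), function(b) {
    which(freqs >= b[1] & freqs < b[2])
  })
  out <- matrix(0, n, 2 * length(eegBands) + 2 + 1)
  for (e in seq_len(n)) {
    feats <- numeric(0)
    for (ch in 1:2) {
      ps <- Mod(stats::fft(sig[e, ch, ]))^2
      ps <- ps[2:(spe %/% 2 + 1)]
      feats <- c(feats, vapply(bandIdx, function(ix) log(sum(ps[ix]) + 1e-12),
        numeric(1)))
    }
    ps <- Mod(stats::fft(sig[e, 3, ]))^2
    ps <- ps[2:(spe %/% 2 + 1)]
    feats <- c(feats, vapply(eogIdx, function(ix) log(sum(ps[ix]) + 1e-12),
      numeric(1)))
    feats <- c(feats, log(sqrt(mean(sig[e, 4, ]^2)) + 1e-12))
    out[e, ] <- feats
  }
  colnames(out) <- c(
    paste0("eeg1_", c("delta", "theta", "alpha", "sigma", "beta")),
    paste0("eeg2_", c("delta", "theta", "alpha", "sigma", "beta")),
    "eog_low", "eog_mid", "emg_rms"
  )
  out
}
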