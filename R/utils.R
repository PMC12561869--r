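# Shared constants and small helpers.

#' Sleep stage codes
#'
#' Stages are coded as integers `0:4` throughout the package:
#' 0 = W (wake), 1 = N1, 2 = N2, 3 = N3, 4 = REM. Slots excluded from
#' scoring (movement time, unscored) carry the sentinel `-1`.
#'
#' @return `stageNames()` returns the five stage names in code order.
#' @export
stageNames <- function() c("W", "N1", "N2", "N3", "REM")

.N_STAGES <- 5L
.EXCLUDED <- -1L

#' Canonical channel order for epoch sets
#'
#' The fixed four-channel montage consumed by the classifier: two EEG
#' derivations, one horizontal EOG and one submental EMG.
#'
#' @return character vector of length 4.
#' @export
channelOrder <- function() {
  c("EEG Fpz-Cz", "EEG Pz-Oz", "EOG horizontal", "EMG submental")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic derived seeds, kept below .Machine$integer.max.
deriveSeed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + as.numeric(i) * 16807) %% 2147483399)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
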