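#' Root-mean-square of a signal
#'
#' For multichannel input the RMS is taken over all samples of all channels,
#' which is the convention used for scene-level normalization.
#'
#' @param x numeric vector, matrix, or `waveform`.
#' @return scalar RMS.
#' @export
rms <- function(x) {
  if (inherits(x, "waveform")) x <- x$samples
  sqrt(mean(x^2))
}

#' Amplitude/decibel conversions
#'
#' @param a amplitude ratio.
#' @param db level in dB.
#' @return converted value.
#' @export
amplitude_to_db <- function(a) 20 * log10(a)

#' @rdname amplitude_to_db
#' @export
db_to_amplitude <- function(db) 10^(db / 20)

# stop() wrappers so tests can distinguish error classes
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("gainlisten_config_error", "error")))
}
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("gainlisten_input_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic non-negative integer hash of a string (used for word
# modulation signatures; must be stable across sessions and platforms).
string_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% 1000003
  h
}
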