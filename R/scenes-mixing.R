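# Level and SNR arithmetic, and per-example signal augmentations.
#
# Digital SPL reference: a full-scale RMS of 1.0 corresponds to 100 dB SPL.
# All level arithmetic is relative, so the constant is arbitrary but fixed;
# it keeps 50-70 dB SPL sources in a well-conditioned float range.

SPL_REF_DB <- 100

#' Measure the level of a waveform in dB SPL
#'
#' @param w `waveform` (or numeric).
#' @return level in dB SPL under the package's digital reference
#'   (RMS 1.0 = 100 dB SPL).
#' @export
measure_level <- function(w) {
  r <- rms(w)
  if (r == 0) return(-Inf)
  SPL_REF_DB + 20 * log10(r)
}

#' Scale a waveform to a target sound pressure level
#'
#' @param w nonsilent `waveform`.
#' @param level target level, dB SPL.
#' @return scaled `waveform`.
#' @export
set_level <- function(w, level) {
  r <- rms(w)
  if (r == 0) stop_input("cannot scale an all-zero waveform to a level")
  scale <- db_to_amplitude(level - measure_level(w))
  w$samples <- w$samples * scale
  w
}

#' Mix a target into a distractor bed at a given SNR
#'
#' Scales the target so that `20 log10(rms(target) / rms(distractors))`
#' equals `snr`, sums the two, and RMS-normalizes the mixture to
#' `normalize_rms` (0.02 by default; pass `NA` to skip normalization).
#'
#' @param target `waveform` (mono or stereo).
#' @param distractor_sum `waveform`, same shape and rate as `target`.
#' @param snr signal-to-noise ratio, dB.
#' @param normalize_rms mixture RMS after normalization.
#' @return mixture `waveform`; attributes `target_scale` (the pre-sum
#'   target gain) and `prenorm_rms` retain the linear audit trail.
#' @export
mix_at_snr <- function(target, distractor_sum, snr, normalize_rms = 0.02) {
  if (!identical(dim(target$samples), dim(distractor_sum$samples))) {
    stop_input("target and distractor waveforms must have equal shape")
  }
  if (abs(target$sample_rate - distractor_sum$sample_rate) > 1e-9) {
    stop_input("target and distractor sample rates differ")
  }
  rd <- rms(distractor_sum)
  rt <- rms(target)
  if (rd == 0 && is.finite(snr)) {
    stop_input("silent distractor with finite snr")
  }
  if (rt == 0) stop_input("silent target")
  scale <- rd / rt * db_to_amplitude(snr)
  pre <- target$samples * scale + distractor_sum$samples
  out <- waveform(pre, target$sample_rate)
  pr <- rms(out)
  if (!is.na(normalize_rms)) out$samples <- out$samples * (normalize_rms / pr)
  attr(out, "target_scale") <- scale
  attr(out, "prenorm_rms") <- pr
  out
}

#' Normalize a waveform to a fixed RMS
#'
#' @param w `waveform`; all-zero input is returned unchanged (a silent cue
#'   stays silent).
#' @param target_rms target RMS (default 0.02).
#' @return scaled `waveform`.
#' @export
normalize_rms <- function(w, target_rms = 0.02) {
  r <- rms(w)
  if (r > 0) w$samples <- w$samples * (target_rms / r)
  w
}

#' Per-example signal augmentations
#'
#' `"bandpass"`: with probability `prob`, applies a Butterworth band-pass
#' whose low cutoff, high cutoff and order are drawn uniformly from the
#' configured ranges (defaults 40-400 Hz, 4-16 kHz, order 1-4); cutoffs
#' are clamped below Nyquist. `"timeshift"`: shifts the utterance forward
#' or backward (equiprobable) by up to 50% of the labeled word's duration,
#' constrained so the labeled word still overlaps the temporal midpoint of
#' the material. Draws use R's global RNG.
#'
#' @param u `utterance`.
#' @param kind `"bandpass"` or `"timeshift"`.
#' @param prob application probability for the bandpass augmentation.
#' @param low_range,high_range,order_range bandpass parameter ranges.
#' @return augmented `utterance`; applied parameters are recorded in
#'   `u$augmentations`.
#' @export
augment_signal <- function(u, kind = c("bandpass", "timeshift"), prob = 0.5,
                           low_range = c(40, 400),
                           high_range = c(4000, 16000),
                           order_range = c(1, 4)) {
  kind <- match.arg(kind)
  fs <- u$waveform$sample_rate
  if (kind == "bandpass") {
    if (stats::runif(1) >= prob) {
      u$augmentations$bandpass <- NULL
      return(u)
    }
    lo <- stats::runif(1, low_range[1], low_range[2])
    hi <- stats::runif(1, high_range[1], high_range[2])
    hi <- min(hi, 0.95 * fs / 2)
    lo <- min(lo, hi / 4)
    ord <- sample(order_range[1]:order_range[2], 1)
    bf <- signal::butter(ord, c(lo, hi) / (fs / 2), type = "pass")
    x <- as.numeric(signal::filter(bf, u$waveform$samples[1, ]))
    u$waveform <- waveform(x, fs)
    u$augmentations$bandpass <- list(low = lo, high = hi, order = ord)
    return(u)
  }
  # timeshift
  mid_idx <- middle_word_index(u)
  b <- u$word_boundaries
  word_dur <- b[mid_idx, "end"] - b[mid_idx, "start"]
  mag <- stats::runif(1, 0, 0.5 * word_dur)
  shift <- sample(c(-1, 1), 1) * mag
  centre <- u$duration / 2
  # keep the labeled word overlapping the midpoint after shifting
  lo_ok <- centre - b[mid_idx, "end"] + 1 / fs
  hi_ok <- centre - b[mid_idx, "start"] - 1 / fs
  shift <- min(max(shift, lo_ok), hi_ok)
  ns <- round(shift * fs)
  x <- u$waveform$samples[1, ]
  n <- length(x)
  y <- numeric(n)
  if (ns >= 0) {
    y[(ns + 1):n] <- x[seq_len(n - ns)]
  } else {
    y[seq_len(n + ns)] <- x[(-ns + 1):n]
  }
  u$waveform <- waveform(y, fs)
  u$word_boundaries <- b + ns / fs
  u$augmentations$timeshift <- ns / fs
  u
}
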