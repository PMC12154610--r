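# Stimulus manipulations: inharmonic jitter, whispering, shaped noises.

#' Jitter the harmonic components of an utterance
#'
#' Each component above the fundamental is shifted by an independent
#' uniform draw bounded by `+/- max_shift * f0`, accepted by rejection
#' sampling until all adjacent component spacings are at least
#' `min_spacing` Hz. The accepted jitter pattern is recorded on the result
#' so the identical pattern can be re-applied to the other utterances of a
#' trial (pass it via `pattern`).
#'
#' @param u harmonic `utterance`.
#' @param max_shift maximum shift as a fraction of f0 (default 0.30).
#' @param min_spacing minimum adjacent component spacing in Hz (default 30).
#' @param pattern optional stored jitter pattern (relative shifts) to
#'   re-apply instead of sampling.
#' @param max_attempts rejection-sampling bound before declaring the
#'   constraint infeasible.
#' @return inharmonic `utterance` with `jitter_pattern` set.
#' @export
jitter_harmonics <- function(u, max_shift = 0.30, min_spacing = 30,
                             pattern = NULL, max_attempts = 1000) {
  if (u$harmonicity != "harmonic") {
    stop_input("jitter_harmonics expects a harmonic utterance")
  }
  f0 <- u$talker$f0
  K <- u$n_components
  if (max_shift == 0 && is.null(pattern)) pattern <- numeric(K)
  if (is.null(pattern)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      cand <- c(0, stats::runif(K - 1, -max_shift, max_shift))
      freqs <- seq_len(K) * f0 + cand * f0
      if (K == 1 || all(diff(freqs) >= min_spacing)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop_config("could not satisfy the ", min_spacing,
                  " Hz spacing constraint in ", max_attempts,
                  " attempts (constraint infeasible for f0 = ", f0, ")")
    }
    pattern <- cand
  } else {
    if (length(pattern) != K) {
      stop_config("stored jitter pattern length does not match ",
                  "the component count")
    }
  }
  out <- synth_utterance(u$talker, u$word_sequence, u$duration,
                         u$waveform$sample_rate, seed = u$seed,
                         f_cap = u$f_cap, jitter_pattern = pattern)
  out
}

#' Breath-noise high-pass filter for whispered synthesis
#'
#' A second-order high-pass Butterworth with 3 dB cutoff at 1200 Hz whose
#' (double) zero at z = 1 is moved toward the origin to radius 0.95,
#' restoring a small amount of energy at the bottom of the spectrum.
#'
#' @param sample_rate design sampling rate, Hz.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
whisper_filter <- function(sample_rate) {
  if (sample_rate <= 2400) {
    stop_config("whisper filter needs a sampling rate above 2400 Hz ",
                "(1200 Hz cutoff)")
  }
  hp <- signal::butter(2, 1200 / (sample_rate / 2), type = "high")
  k <- hp$b[1]
  list(b = k * c(1, -2 * 0.95, 0.95^2), a = hp$a)
}

#' Whispered version of an utterance
#'
#' Replaces the periodic excitation with white noise passed through the
#' modified high-pass of [whisper_filter()], shaped by the talker's
#' spectral envelope and the utterance's per-word amplitude modulators.
#' Word boundaries and duration are preserved exactly.
#'
#' @param u `utterance`.
#' @param seed optional seed for the noise excitation.
#' @return `utterance` with `harmonicity = "whispered"`.
#' @export
whisper_transform <- function(u, seed = NULL) {
  fs <- u$waveform$sample_rate
  n <- ncol(u$waveform$samples)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  coefs <- whisper_filter(fs)
  noise <- withr_seed(seed, stats::rnorm(n))
  exc <- as.numeric(signal::filter(coefs$b, coefs$a, noise))
  # impose the talker's spectral envelope in the frequency domain
  X <- stats::fft(exc)
  f <- (0:(n - 1)) * fs / n
  f_fold <- pmin(f, fs - f)
  H <- talker_envelope(u$talker, f_fold)
  shaped <- Re(stats::fft(X * H, inverse = TRUE)) / n
  mods <- word_modulators(u$word_sequence, u$duration, fs,
                          u$talker$language_class)
  x <- shaped * mods$am
  r <- rms(x)
  if (r > 0) x <- x * (0.05 / r)
  out <- u
  out$waveform <- waveform(x, fs)
  out$harmonicity <- "whispered"
  out$jitter_pattern <- numeric(u$n_components)
  out$whisper_seed <- seed
  out
}

#' Synthesize shaped noise
#'
#' `"speech-shaped"` imposes the magnitude spectrum of a reference clip on
#' white noise; `"pink"` imposes a 1/f power spectrum (1/sqrt(f)
#' magnitude).
#'
#' @param kind `"speech-shaped"` or `"pink"`.
#' @param reference reference `waveform` (required for speech-shaped; sets
#'   the sampling rate unless `sample_rate` is given).
#' @param duration output duration, s.
#' @param sample_rate output sampling rate, Hz.
#' @param rms_out output RMS (default 0.02).
#' @return mono `waveform`.
#' @export
shaped_noise <- function(kind = c("speech-shaped", "pink"), reference = NULL,
                         duration, sample_rate = NULL, rms_out = 0.02) {
  kind <- match.arg(kind)
  if (kind == "speech-shaped") {
    if (is.null(reference)) {
      stop_input("speech-shaped noise requires a reference waveform")
    }
    sample_rate <- sample_rate %||% reference$sample_rate
  } else if (is.null(sample_rate)) {
    stop_config("sample_rate required for pink noise")
  }
  n <- round(duration * sample_rate)
  noise <- stats::rnorm(n)
  X <- stats::fft(noise)
  if (kind == "speech-shaped") {
    ref <- colMeans(rbind(reference$samples))
    ref <- if (length(ref) >= n) ref[seq_len(n)] else c(ref, numeric(n - length(ref)))
    mag <- Mod(stats::fft(ref))
  } else {
    j <- 0:(n - 1)
    fold <- pmin(j, n - j)
    mag <- ifelse(fold == 0, 0, 1 / sqrt(fold))
  }
  y <- Re(stats::fft(X * mag, inverse = TRUE)) / n
  r <- rms(y)
  if (r > 0) y <- y * (rms_out / r)
  waveform(y, sample_rate)
}
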