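#' ERB-number scale transforms
#'
#' The ERB-number (equivalent rectangular bandwidth rate) scale approximates
#' the spacing of auditory filters along the cochlea, using the standard
#' Glasberg-Moore form: ERB-number(f) = 21.4 log10(0.00437 f + 1), with
#' filter bandwidth ERB(f) = 24.7 (0.00437 f + 1) Hz.
#'
#' @param f frequency in Hz.
#' @param e ERB-number.
#' @return transformed value(s).
#' @export
erb_number <- function(f) 21.4 * log10(0.00437 * f + 1)

#' @rdname erb_number
#' @export
erb_number_inverse <- function(e) (10^(e / 21.4) - 1) / 0.00437

#' @rdname erb_number
#' @export
erb_bandwidth <- function(f) 24.7 * (0.00437 * f + 1)

#' Center frequencies equally spaced on the ERB-number scale
#'
#' Endpoints are inclusive: the first center frequency is exactly `f_lo` and
#' the last exactly `f_hi`.
#'
#' @param n number of frequencies.
#' @param f_lo,f_hi frequency range in Hz.
#' @return numeric vector of length `n`, strictly increasing.
#' @export
erb_space <- function(n, f_lo, f_hi) {
  if (n < 1) stop_config("need at least one channel")
  if (n == 1) return(f_lo)
  erb_number_inverse(seq(erb_number(f_lo), erb_number(f_hi), length.out = n))
}

#' Gammatone FIR filter bank
#'
#' Builds a bank of 4th-order gammatone filters with center frequencies
#' equally spaced on the ERB-number scale between `f_lo` and `f_hi`
#' (inclusive endpoints), as a finite-impulse-response approximation with
#' impulse responses truncated to `trunc` seconds
#' (`n_taps = floor(trunc * sample_rate)`). Each filter's bandwidth is
#' 1.019 ERB(CF), and each impulse response is normalized to unit magnitude
#' response at its center frequency.
#'
#' @param n_channels number of filters.
#' @param f_lo,f_hi lowest/highest center frequency, Hz.
#' @param sample_rate sampling rate, Hz.
#' @param trunc impulse-response truncation, seconds (default 25 ms).
#' @return object of class `filterbank` with fields `center_freqs`,
#'   `impulse_responses` (n_channels x n_taps), `n_taps`, `sample_rate`.
#' @export
make_filterbank <- function(n_channels, f_lo = 40, f_hi = 20000,
                            sample_rate = 44100, trunc = 0.025) {
  if (n_channels < 1) stop_config("n_channels must be >= 1")
  if (!(0 < f_lo && f_lo < f_hi && f_hi < sample_rate / 2)) {
    stop_config("require 0 < f_lo < f_hi < sample_rate/2")
  }
  cfs <- erb_space(n_channels, f_lo, f_hi)
  n_taps <- floor(trunc * sample_rate)
  tt <- (0:(n_taps - 1)) / sample_rate
  ir <- matrix(0, n_channels, n_taps)
  for (k in seq_len(n_channels)) {
    b <- 1.019 * erb_bandwidth(cfs[k])
    g <- tt^3 * exp(-2 * pi * b * tt) * cos(2 * pi * cfs[k] * tt)
    # normalize to unit gain at CF
    resp <- sum(g * exp(-2i * pi * cfs[k] * tt))
    ir[k, ] <- g / Mod(resp)
  }
  structure(
    list(
      center_freqs = cfs, impulse_responses = ir,
      n_taps = n_taps, sample_rate = sample_rate
    ),
    class = "filterbank"
  )
}

#' Magnitude response of one FIR filter at given frequencies
#'
#' Direct evaluation of the discrete-time Fourier transform of the impulse
#' response; used both internally and as an oracle in tests.
#'
#' @param fb `filterbank`.
#' @param channel filter index.
#' @param freqs frequencies in Hz.
#' @return magnitude response at `freqs`.
#' @export
filter_response <- function(fb, channel, freqs) {
  tt <- (0:(fb$n_taps - 1)) / fb$sample_rate
  vapply(freqs, function(f) {
    Mod(sum(fb$impulse_responses[channel, ] * exp(-2i * pi * f * tt)))
  }, numeric(1))
}

# FFT-based filtering of one mono channel with the whole bank,
# "same"-length center-aligned output. Returns n_filters x n matrix.
# Filter spectra are cached per (filterbank, nfft).
filterbank_apply <- function(fb, x) {
  n <- length(x)
  taps <- fb$n_taps
  nfft <- stats::nextn(n + taps - 1, 2)
  key <- paste0("fbH_", format(fb$center_freqs[1], digits = 12), "_",
                length(fb$center_freqs), "_", fb$sample_rate, "_", nfft)
  H <- cache_get(key, function() {
    irp <- rbind(t(fb$impulse_responses),
                 matrix(0, nfft - taps, nrow(fb$impulse_responses)))
    stats::mvfft(irp)
  })
  X <- stats::fft(c(x, numeric(nfft - n)))
  Y <- Re(stats::mvfft(H * X, inverse = TRUE)) / nfft
  off <- floor((taps - 1) / 2)
  t(Y[off + seq_len(n), , drop = FALSE])
}

#' Resample signals with a Kaiser-windowed sinc filter
#'
#' Zero-phase lowpass sinc interpolation with a Kaiser window; the default
#' width/roll-off/beta correspond to a high-quality anti-aliased resampler.
#' Rows of a matrix input are resampled independently.
#'
#' @param x numeric vector or matrix (rows = channels).
#' @param fs_in,fs_out input/output sampling rates in Hz.
#' @param width kernel half-width in zero crossings (default 64).
#' @param rolloff cutoff as a fraction of the output Nyquist (default 0.94759).
#' @param beta Kaiser window shape parameter (default 14.76965).
#' @return resampled matrix with `round(n * fs_out / fs_in)` columns.
#' @export
resample_kaiser <- function(x, fs_in, fs_out, width = 64,
                            rolloff = 0.94759, beta = 14.76965) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  resample_sinc_cpp(x, fs_in, fs_out, as.integer(width), rolloff, beta)
}

#' Cochleagram of a stereo waveform
#'
#' Simulates the cochlea/auditory-nerve transform: each ear's waveform is
#' convolved with the gammatone bank (center-aligned "same" output),
#' half-wave rectified, compressed by a power nonlinearity, lowpass-filtered
#' and downsampled to `out_rate` with a Kaiser-windowed sinc resampler, and
#' the middle `excerpt` seconds are taken to avoid onset/offset artifacts.
#' The two ears are stacked on the first axis.
#'
#' @param w stereo `waveform` at the filterbank's sampling rate.
#' @param fb `filterbank`.
#' @param compress_exp compressive exponent (default 0.3).
#' @param out_rate output sampling rate in Hz (default 10000).
#' @param excerpt excerpt duration in seconds (default 2).
#' @param resample_width,rolloff,beta resampler kernel parameters
#'   (see [resample_kaiser()]).
#' @return object of class `cochleagram`: `values` is a nonnegative array
#'   of dimension 2 x n_freq x n_time, with `sample_rate = out_rate` and
#'   `freq_axis` the filter center frequencies.
#' @export
cochleagram <- function(w, fb, compress_exp = 0.3, out_rate = 10000,
                        excerpt = 2, resample_width = 64,
                        rolloff = 0.94759, beta = 14.76965) {
  if (n_channels(w) != 2L) {
    stop_input("cochleagram expects a binaural (stereo) waveform; ",
               "use diotic() to duplicate a mono signal")
  }
  if (abs(w$sample_rate - fb$sample_rate) > 1e-9) {
    stop_config("waveform and filterbank sample rates differ")
  }
  if (w$duration < excerpt - 1e-9) {
    stop_input("input duration ", signif(w$duration, 4),
               " s is shorter than the requested excerpt ", excerpt, " s")
  }
  n_ex <- round(excerpt * out_rate)
  nf <- length(fb$center_freqs)
  # detect identical ears once: diotic inputs need only one filtering pass
  ears_equal <- identical(w$samples[1, ], w$samples[2, ])
  per_ear <- function(xe) {
    sub <- filterbank_apply(fb, xe)
    sub[sub < 0] <- 0
    sub <- sub^compress_exp
    res <- resample_kaiser(sub, fb$sample_rate, out_rate,
                           width = resample_width, rolloff = rolloff,
                           beta = beta)
    n_out <- ncol(res)
    if (n_out < n_ex) stop_input("resampled signal shorter than excerpt")
    start <- floor((n_out - n_ex) / 2)
    res <- res[, start + seq_len(n_ex), drop = FALSE]
    # the lowpass sinc kernel can ring slightly below zero; the
    # auditory-nerve representation is nonnegative, so clip
    res[res < 0] <- 0
    res
  }
  left <- per_ear(w$samples[1, ])
  right <- if (ears_equal) left else per_ear(w$samples[2, ])
  vals <- array(0, c(2, nf, n_ex))
  vals[1, , ] <- left
  vals[2, , ] <- right
  structure(
    list(values = vals, sample_rate = out_rate, freq_axis = fb$center_freqs),
    class = "cochleagram"
  )
}

#' @export
print.cochleagram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<cochleagram: %d x %d x %d @ %g Hz>\n", d[1], d[2], d[3],
              x$sample_rate))
  invisible(x)
}

#' Save / load a cochleagram
#'
#' Serialized as an RDS file holding the values array together with axis
#' metadata (frequency axis and frame rate).
#'
#' @param cg `cochleagram`.
#' @param path file path.
#' @return `save_cochleagram` returns `path` invisibly; `load_cochleagram`
#'   returns the `cochleagram`.
#' @export
save_cochleagram <- function(cg, path) {
  saveRDS(cg, path)
  invisible(path)
}

#' @rdname save_cochleagram
#' @export
load_cochleagram <- function(path) {
  cg <- readRDS(path)
  if (!inherits(cg, "cochleagram")) stop_input("not a cochleagram file: ", path)
  cg
}
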