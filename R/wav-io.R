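#' Audio waveform container
#'
#' A light S3 container for mono or stereo audio. `samples` is stored as a
#' channels-by-time numeric matrix (a vector is treated as mono).
#'
#' @param samples numeric vector (mono) or matrix with 1 or 2 rows.
#' @param sample_rate sampling rate in Hz.
#' @return object of class `waveform` with fields `samples`, `sample_rate`,
#'   and `duration` (seconds).
#' @export
waveform <- function(samples, sample_rate) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  if (!is.matrix(samples)) stop_input("samples must be a vector or matrix")
  if (!nrow(samples) %in% c(1L, 2L)) {
    stop_input("waveform must have 1 or 2 channels, got ", nrow(samples))
  }
  if (!all(is.finite(samples))) stop_input("waveform contains non-finite values")
  if (sample_rate <= 0) stop_config("sample_rate must be positive")
  structure(
    list(
      samples = samples,
      sample_rate = sample_rate,
      duration = ncol(samples) / sample_rate
    ),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform: %d channel(s), %.4g s @ %g Hz>\n",
    nrow(x$samples), x$duration, x$sample_rate
  ))
  invisible(x)
}

n_channels <- function(w) nrow(w$samples)

#' Duplicate a mono waveform to both ears
#'
#' Diotic presentation: the identical signal is delivered to the left and
#' right channels, removing all binaural spatial cues.
#'
#' @param w mono `waveform`.
#' @return stereo `waveform`.
#' @export
diotic <- function(w) {
  if (n_channels(w) == 2L) return(w)
  waveform(rbind(w$samples[1, ], w$samples[1, ]), w$sample_rate)
}

#' Read a RIFF WAV file
#'
#' Supports uncompressed PCM (8/16/24/32-bit integer) and IEEE float32
#' formats. Samples are returned as floats in \[-1, 1\].
#'
#' @param path file path.
#' @return `waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop_input("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    stop_input("not a WAVE file: ", path)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      extra <- sz - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop_input("missing fmt/data chunk: ", path)
  bits <- fmt$bits
  if (fmt$audio_format == 3L || (fmt$audio_format == 65534L && bits == 32L)) {
    x <- readBin(data_raw, "double", length(data_raw) / 4, size = 4, endian = "little")
  } else if (fmt$audio_format == 1L || fmt$audio_format == 65534L) {
    if (bits == 16L) {
      x <- readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                   signed = TRUE, endian = "little") / 32768
    } else if (bits == 8L) {
      x <- (readBin(data_raw, "integer", length(data_raw), size = 1,
                    signed = FALSE, endian = "little") - 128) / 128
    } else if (bits == 32L) {
      x <- readBin(data_raw, "integer", length(data_raw) / 4, size = 4,
                   endian = "little") / 2147483648
    } else if (bits == 24L) {
      n <- length(data_raw) / 3
      b <- matrix(as.integer(data_raw), nrow = 3)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      x <- v / 8388608
    } else {
      stop_input("unsupported PCM bit depth: ", bits)
    }
  } else {
    stop_input("unsupported WAV audio format code: ", fmt$audio_format)
  }
  nc <- fmt$n_channels
  waveform(matrix(x, nrow = nc), fmt$sample_rate)
}

#' Write a RIFF WAV file
#'
#' @param w `waveform`.
#' @param path output path.
#' @param format `"float32"` (default) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  x <- as.vector(w$samples) # interleaved: column-major over channels x time
  nc <- n_channels(w)
  bits <- if (format == "float32") 32L else 16L
  bytes_per <- bits %/% 8L
  data_size <- length(x) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (format == "float32") 3L else 1L, con, size = 2, endian = "little")
  writeBin(nc, con, size = 2, endian = "little")
  writeBin(as.integer(w$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$sample_rate * nc * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(nc * bytes_per), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(x, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(pmax(-32768, pmin(32767, round(x * 32768)))), con,
             size = 2, endian = "little")
  }
  invisible(path)
}
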