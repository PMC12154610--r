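# Synthetic talkers and labeled utterances.
#
# A talker is an additive-synthesis voice: a fundamental frequency (f0), a
# smooth spectral envelope (tilt plus formant-like bumps), and a "sex"
# class. Two classes with disjoint f0 ranges stand in for female/male
# talkers so the same/different-sex analyses can be run without real
# speech. A "word" is a deterministic amplitude/frequency-modulation
# signature imposed on the harmonic stack; word signatures are drawn from a
# per-language inventory so distractor-language contrasts are possible.

#' Synthetic talker specification
#'
#' @param talker_id identifier string.
#' @param sex_class `"A"` or `"B"`; the two classes have disjoint f0 ranges
#'   (80-160 Hz and 170-320 Hz).
#' @param f0 fundamental frequency, Hz; must lie in the class range.
#' @param envelope_params spectral-envelope descriptor: list with `tilt`
#'   and vectors `bump_center`, `bump_amp`, `bump_bw`.
#' @param language_class language inventory identifier (default `"L1"`).
#' @return list of class `talker_spec`.
#' @export
talker_spec <- function(talker_id, sex_class, f0, envelope_params,
                        language_class = "L1") {
  ranges <- list(A = c(80, 160), B = c(170, 320))
  if (!sex_class %in% names(ranges)) stop_config("sex_class must be A or B")
  r <- ranges[[sex_class]]
  if (f0 < r[1] || f0 > r[2]) {
    stop_config("f0 ", f0, " outside the ", sex_class, " class range [",
                r[1], ", ", r[2], "]")
  }
  structure(list(talker_id = talker_id, sex_class = sex_class, f0 = f0,
                 envelope_params = envelope_params,
                 language_class = language_class),
            class = "talker_spec")
}

#' Sample a bank of synthetic talkers
#'
#' f0 is uniform within each class range; each talker gets a random spectral
#' tilt and two formant-like envelope bumps whose centers depend on the
#' class. Uses R's global RNG.
#'
#' @param n_per_class talkers per sex class.
#' @param language_class language inventory for all talkers.
#' @return list of `talker_spec`.
#' @export
make_talker_bank <- function(n_per_class = 2, language_class = "L1") {
  ranges <- list(A = c(80, 160), B = c(170, 320))
  out <- list()
  for (cls in c("A", "B")) {
    for (i in seq_len(n_per_class)) {
      f0 <- stats::runif(1, ranges[[cls]][1], ranges[[cls]][2])
      centers <- if (cls == "A") c(stats::runif(1, 300, 700),
                                   stats::runif(1, 900, 1800))
                 else c(stats::runif(1, 400, 900), stats::runif(1, 1200, 2400))
      env <- list(
        tilt = stats::runif(1, 0.3, 1),
        bump_center = centers,
        bump_amp = stats::runif(2, 0.8, 2.5),
        bump_bw = centers * stats::runif(2, 0.15, 0.3)
      )
      out[[length(out) + 1]] <-
        talker_spec(sprintf("%s%02d", cls, i), cls, f0, env, language_class)
    }
  }
  out
}

# smooth spectral envelope of a talker evaluated at frequencies f (Hz)
talker_envelope <- function(talker, f) {
  ep <- talker$envelope_params
  base <- (1 + f / 300)^(-ep$tilt)
  bump <- numeric(length(f))
  for (j in seq_along(ep$bump_center)) {
    bump <- bump + ep$bump_amp[j] *
      exp(-(f - ep$bump_center[j])^2 / (2 * ep$bump_bw[j]^2))
  }
  base * (1 + bump)
}

#' Deterministic word modulation signature
#'
#' Maps a (word, language inventory) pair to a fixed amplitude- and
#' frequency-modulation signature via a stable string hash, so the same
#' word always sounds the same within a language.
#'
#' @param word word label.
#' @param language_class language inventory identifier.
#' @return list with `am_rate` (Hz), `am_depth`, `am_phase`, `fm_rate`
#'   (Hz), `fm_depth` (fractional f0 excursion).
#' @export
word_signature <- function(word, language_class = "L1") {
  h <- string_hash(paste0(language_class, ":", word))
  list(
    am_rate = 2 + (h %% 49) / 4,                      # 2 .. 14 Hz
    am_depth = 0.6 + ((h %/% 49) %% 9) / 20,          # 0.6 .. 1.0
    am_phase = ((h %/% 7) %% 17) / 17 * 2 * pi,
    # frequency contours are disabled by default: FM sidebands would smear
    # the component peaks, and the harmonic structure of the synthetic
    # voices is kept exact (components sit at integer multiples of f0)
    fm_rate = 0.8 + ((h %/% 441) %% 13) / 4,          # 0.8 .. 3.8 Hz
    fm_depth = 0,
    # formant-like spectral emphasis: a word-specific bump whose center is
    # a fixed fraction of the synthesis bandwidth
    bump_frac = 0.15 + ((h %/% 3) %% 11) / 11 * 0.6,
    bump_amp = 2 + ((h %/% 33) %% 5) / 2               # 2 .. 4
  )
}

# per-sample AM envelope, fractional FM track, word index per sample, and
# the per-word signatures, over the whole utterance
word_modulators <- function(words, duration, sample_rate, language_class) {
  n <- round(duration * sample_rate)
  nw <- length(words)
  am <- numeric(n)
  fm <- numeric(n)
  ws <- integer(n)
  sigs <- vector("list", nw)
  edges <- round(seq(0, n, length.out = nw + 1))
  for (i in seq_len(nw)) {
    idx <- (edges[i] + 1):edges[i + 1]
    tw <- (seq_along(idx) - 1) / sample_rate
    sig <- word_signature(words[i], language_class)
    sigs[[i]] <- sig
    env <- (1 - sig$am_depth) +
      sig$am_depth * 0.5 * (1 + sin(2 * pi * sig$am_rate * tw + sig$am_phase))
    ramp_n <- min(round(0.015 * sample_rate), length(idx) %/% 4)
    if (ramp_n > 0) {
      r <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
      env[seq_len(ramp_n)] <- env[seq_len(ramp_n)] * r
      env[length(env) - ramp_n + seq_len(ramp_n)] <-
        env[length(env) - ramp_n + seq_len(ramp_n)] * rev(r)
    }
    am[idx] <- env
    fm[idx] <- sig$fm_depth * sin(2 * pi * sig$fm_rate * tw)
    ws[idx] <- i
  }
  list(am = am, fm = fm, word_of_sample = ws, signatures = sigs,
       edges = edges)
}

#' Synthesize a labeled utterance
#'
#' Additive synthesis: a stack of components at multiples of the talker's
#' f0 (optionally jittered), weighted by the talker's spectral envelope,
#' with per-word amplitude- and frequency-modulation signatures. Word
#' boundaries tile the duration evenly. The output is deterministic given
#' (talker, words, seed).
#'
#' @param talker `talker_spec`.
#' @param words nonempty character vector of word labels.
#' @param duration utterance duration in seconds (> 0).
#' @param sample_rate sampling rate, Hz.
#' @param seed integer seed for the component phases; if `NULL` one is
#'   drawn from the current RNG (and recorded, so the utterance can be
#'   re-synthesized).
#' @param f_cap highest component frequency, Hz (default
#'   `min(0.45 * sample_rate, 6000)`).
#' @param jitter_pattern optional per-component relative frequency shifts
#'   (fractions of f0; first entry must be 0).
#' @return object of class `utterance` with fields `waveform` (mono),
#'   `word_sequence`, `word_boundaries` (start/end matrix, s), `talker`,
#'   `harmonicity`, `jitter_pattern`, plus the synthesis recipe.
#' @export
synth_utterance <- function(talker, words, duration, sample_rate = 44100,
                            seed = NULL, f_cap = NULL,
                            jitter_pattern = NULL) {
  if (length(words) < 1) stop_input("need at least one word")
  if (duration <= 0) stop_input("duration must be positive")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  f_cap <- f_cap %||% min(0.45 * sample_rate, 6000)
  f0 <- talker$f0
  K <- max(1, floor(f_cap / f0))
  if (is.null(jitter_pattern)) jitter_pattern <- numeric(K)
  if (length(jitter_pattern) != K || abs(jitter_pattern[1]) > 1e-12) {
    stop_config("jitter_pattern must have one entry per component, ",
                "with no shift on the fundamental")
  }
  n <- round(duration * sample_rate)
  mods <- word_modulators(words, duration, sample_rate,
                          talker$language_class)
  comp_freqs <- seq_len(K) * f0 + jitter_pattern * f0
  amps <- talker_envelope(talker, comp_freqs)
  phases <- withr_seed(seed, stats::runif(K, 0, 2 * pi))
  # word-specific spectral emphasis of the component amplitudes
  nw <- length(words)
  wgain <- matrix(1, nw, K)
  bw <- 0.12 * f_cap
  for (i in seq_len(nw)) {
    sig <- mods$signatures[[i]]
    wc <- sig$bump_frac * f_cap
    wgain[i, ] <- 1 + sig$bump_amp * exp(-(comp_freqs - wc)^2 / (2 * bw^2))
  }
  x <- numeric(n)
  for (k in seq_len(K)) {
    inst_f <- comp_freqs[k] * (1 + mods$fm)
    ph <- 2 * pi * cumsum(inst_f) / sample_rate + phases[k]
    x <- x + amps[k] * wgain[mods$word_of_sample, k] * sin(ph)
  }
  x <- x * mods$am
  r <- rms(x)
  if (r > 0) x <- x * (0.05 / r)
  nw <- length(words)
  bounds <- cbind(start = (seq_len(nw) - 1) * duration / nw,
                  end = seq_len(nw) * duration / nw)
  structure(
    list(
      waveform = waveform(x, sample_rate),
      word_sequence = words,
      word_boundaries = bounds,
      talker = talker,
      harmonicity = if (any(jitter_pattern != 0)) "inharmonic" else "harmonic",
      jitter_pattern = jitter_pattern,
      seed = seed, f_cap = f_cap, duration = duration,
      n_components = K, component_freqs = comp_freqs
    ),
    class = "utterance"
  )
}

# evaluate expr under a temporary seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.utterance <- function(x, ...) {
  cat(sprintf("<utterance: \"%s\" by %s (%s), %.3g s, %s>\n",
              paste(x$word_sequence, collapse = " "),
              x$talker$talker_id, x$talker$sex_class, x$duration,
              x$harmonicity))
  invisible(x)
}

#' Index of the middle (labeled) word of an utterance
#'
#' The labeled word of a clip is the one overlapping the temporal midpoint
#' of the material (which maps to the 1-second mark of a 2-second excerpt
#' taken from the middle of 2.5-second material).
#'
#' @param u `utterance`.
#' @return integer word index.
#' @export
middle_word_index <- function(u) {
  mid <- u$duration / 2
  b <- u$word_boundaries
  idx <- which(b[, "start"] <= mid & b[, "end"] > mid)
  if (length(idx) == 0) idx <- which.min(abs((b[, 1] + b[, 2]) / 2 - mid))
  idx[1]
}
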