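# Synthetic talkers, stimulus manipulations, level/SNR arithmetic, and
# scene assembly.

mk_talker <- function(f0 = 110, cls = "A") {
  talker_spec("T1", cls, f0,
              list(tilt = 0.5, bump_center = c(400, 700),
                   bump_amp = c(1.5, 1), bump_bw = c(120, 200)))
}

test_that("harmonic utterances have spectral peaks at multiples of f0", {
  tk <- mk_talker(110)
  u <- synth_utterance(tk, "ember", duration = 2, sample_rate = 4000,
                       seed = 5, f_cap = 1500)
  # oracle: peak-picking on the magnitude spectrum. The word's amplitude
  # modulation creates sidebands around each component, so the carrier is
  # identified as the dominant bin within each harmonic's window; every
  # carrier must sit within 1 Hz of an integer multiple of f0.
  x <- u$waveform$samples[1, ]
  n <- length(x)
  sp <- Mod(fft(x))[seq_len(n %/% 2)]
  f <- (seq_len(n %/% 2) - 1) * u$waveform$sample_rate / n
  n_found <- 0
  for (k in 1:13) {
    win <- which(abs(f - k * 110) < 40)
    if (max(sp[win]) < 0.05 * max(sp)) next
    fpk <- f[win][which.max(sp[win])]
    expect_lt(abs(fpk - k * 110), 1)
    n_found <- n_found + 1
  }
  expect_gt(n_found, 3)
})

test_that("utterance synthesis is deterministic and talker-specific", {
  tk <- mk_talker(110)
  u1 <- synth_utterance(tk, c("dune", "ember", "frost"), 2.5, 2000, seed = 9)
  u2 <- synth_utterance(tk, c("dune", "ember", "frost"), 2.5, 2000, seed = 9)
  expect_identical(u1$waveform$samples, u2$waveform$samples)
  tk2 <- mk_talker(250, "B")
  u3 <- synth_utterance(tk2, c("dune", "ember", "frost"), 2.5, 2000, seed = 9)
  expect_false(isTRUE(all.equal(u1$waveform$samples, u3$waveform$samples)))
  # boundaries tile the duration
  expect_equal(u1$word_boundaries[, "start"], c(0, 2.5 / 3, 5 / 3),
               tolerance = 1e-12)
  expect_equal(middle_word_index(u1), 2)
  expect_error(synth_utterance(tk, character(0), 2, 2000),
               class = "gainlisten_input_error")
  expect_error(synth_utterance(tk, "dune", 0, 2000),
               class = "gainlisten_input_error")
})

test_that("harmonic jitter respects the spacing constraint", {
  tk <- mk_talker(110)
  u <- synth_utterance(tk, c("dune", "ember", "frost"), 2.5, 2000, seed = 3,
                       f_cap = 900)
  set.seed(31)
  uj <- jitter_harmonics(u, max_shift = 0.30, min_spacing = 30)
  expect_equal(uj$harmonicity, "inharmonic")
  freqs <- uj$component_freqs
  expect_true(all(diff(freqs) >= 30))
  expect_true(all(abs(uj$jitter_pattern[-1]) <= 0.30))
  expect_equal(uj$jitter_pattern[1], 0)
  # zero shift reproduces the input bit for bit
  u0 <- jitter_harmonics(u, max_shift = 0)
  expect_identical(u0$waveform$samples, u$waveform$samples)
  # durations and boundaries survive the manipulation exactly
  expect_identical(uj$word_boundaries, u$word_boundaries)
  expect_equal(ncol(uj$waveform$samples), ncol(u$waveform$samples))
})

test_that("a stored jitter pattern reapplies to identical frequencies", {
  tk <- mk_talker(120)
  u_target <- synth_utterance(tk, c("dune", "ember", "frost"), 2.5, 2000,
                              seed = 4, f_cap = 900)
  u_cue <- synth_utterance(tk, c("grove", "arbor", "breeze"), 2.5, 2000,
                           seed = 5, f_cap = 900)
  set.seed(32)
  jt <- jitter_harmonics(u_target)
  jc <- jitter_harmonics(u_cue, pattern = jt$jitter_pattern)
  expect_identical(jc$component_freqs, jt$component_freqs)
})

test_that("infeasible jitter constraints raise a configuration error", {
  tk <- mk_talker(80)
  u <- synth_utterance(tk, "dune", 1, 2000, seed = 6, f_cap = 800)
  # min spacing above (1 - 2 * max_shift) * f0 makes rejection hopeless
  set.seed(33)
  expect_error(
    jitter_harmonics(u, max_shift = 0.45, min_spacing = 70,
                     max_attempts = 50),
    class = "gainlisten_config_error"
  )
})

test_that("the whisper filter has the documented zero structure", {
  wf <- whisper_filter(44100)
  z <- polyroot(rev(wf$b))
  expect_equal(sort(Mod(z)), c(0.95, 0.95), tolerance = 1e-9)
  expect_equal(sort(Re(z)), c(0.95, 0.95), tolerance = 1e-9)
  # DC gain strictly positive (the unmodified high-pass has zero DC gain)
  expect_gt(sum(wf$b) / sum(wf$a), 0)
  # magnitude response is monotonically nondecreasing from 100 Hz to 4 kHz
  # (up to float-level ripple where the response saturates)
  f <- seq(100, 4000, by = 50)
  H <- vapply(f, function(fr) {
    z1 <- exp(-2i * pi * fr / 44100)
    Mod(sum(wf$b * z1^(0:2)) / sum(wf$a * z1^(0:2)))
  }, numeric(1))
  expect_true(all(diff(H) > -1e-4))
  expect_error(whisper_filter(2000), class = "gainlisten_config_error")
})

test_that("whispering preserves structure but removes harmonicity", {
  tk <- mk_talker(110)
  u <- synth_utterance(tk, c("dune", "ember", "frost"), 2.5, 8000, seed = 7,
                       f_cap = 900)
  set.seed(34)
  uw <- whisper_transform(u)
  expect_equal(uw$harmonicity, "whispered")
  expect_identical(uw$word_boundaries, u$word_boundaries)
  expect_equal(ncol(uw$waveform$samples), ncol(u$waveform$samples))
  # harmonicity is gone: the fraction of power concentrated within narrow
  # bands around multiples of f0 drops from near-total to near the chance
  # share of the spectrum occupied by those bands
  harm_frac <- function(w, f0) {
    x <- w$samples[1, ]
    n <- length(x)
    sp <- Mod(fft(x))[seq_len(n %/% 2)]^2
    f <- (seq_len(n %/% 2) - 1) * w$sample_rate / n
    near <- abs(f - f0 * round(f / f0)) < 5
    sum(sp[near]) / sum(sp)
  }
  expect_gt(harm_frac(u$waveform, 110), 0.8)
  expect_lt(harm_frac(uw$waveform, 110), 0.4)
})

test_that("speech-shaped noise matches the reference spectrum per band", {
  tk <- mk_talker(130)
  set.seed(35)
  u <- synth_utterance(tk, c("dune", "ember", "frost"), 2.5, 8000, seed = 8,
                       f_cap = 3000)
  noise <- shaped_noise("speech-shaped", reference = u$waveform,
                        duration = 2.5)
  expect_equal(noise$sample_rate, 8000)
  expect_equal(ncol(noise$samples), 20000)
  centers <- c(200, 400, 800, 1600)
  ref_db <- band_energies_db(u$waveform, centers)
  # smooth the noise spectrum estimate by averaging band energies over
  # independent realizations (the reference is a line spectrum, so a single
  # realization has few effective degrees of freedom per band)
  noise_pow <- Reduce(`+`, lapply(1:8, function(i) {
    ni <- shaped_noise("speech-shaped", reference = u$waveform,
                       duration = 2.5)
    10^(band_energies_db(ni, centers) / 10)
  }))
  noise_db <- 10 * log10(noise_pow / 8)
  # matching shape within 3 dB per third-octave band
  ref_db <- ref_db - mean(ref_db)
  noise_db <- noise_db - mean(noise_db)
  expect_lt(max(abs(ref_db - noise_db)), 3)
  expect_error(shaped_noise("speech-shaped", duration = 1),
               class = "gainlisten_input_error")
})

test_that("pink noise has constant per-octave energy", {
  set.seed(36)
  noise <- shaped_noise("pink", duration = 4, sample_rate = 16000)
  centers <- c(125, 250, 500, 1000, 2000, 4000)
  oct_db <- vapply(centers, function(fc) {
    x <- noise$samples[1, ]
    n <- length(x)
    sp <- Mod(fft(x))[seq_len(n %/% 2)]^2
    f <- (seq_len(n %/% 2) - 1) * noise$sample_rate / n
    10 * log10(sum(sp[f >= fc / sqrt(2) & f < fc * sqrt(2)]))
  }, numeric(1))
  expect_lt(max(oct_db) - min(oct_db), 1.5)
})

test_that("level arithmetic behaves like decibels", {
  set.seed(37)
  w <- waveform(rnorm(22050, sd = 0.01), 44100)
  w60 <- set_level(w, 60)
  expect_equal(measure_level(w60), 60, tolerance = 1e-9)
  # doubling the amplitude adds 20 log10(2) dB
  w2 <- w60; w2$samples <- w2$samples * 2
  expect_equal(measure_level(w2) - measure_level(w60), 20 * log10(2),
               tolerance = 1e-9)
  # idempotent at the same target
  expect_equal(set_level(w60, 60)$samples, w60$samples, tolerance = 1e-12)
  expect_error(set_level(waveform(numeric(100), 44100), 60),
               class = "gainlisten_input_error")
})

test_that("two independent 61.99 dB sources sum to 65 dB", {
  set.seed(38)
  sums <- vapply(1:40, function(i) {
    a <- set_level(waveform(rnorm(8000), 8000), 61.99)
    b <- set_level(waveform(rnorm(8000), 8000), 61.99)
    measure_level(waveform(a$samples + b$samples, 8000))
  }, numeric(1))
  expect_equal(mean(sums), 65, tolerance = 0.1)
})

test_that("mix_at_snr hits the requested SNR and output RMS exactly", {
  set.seed(39)
  t_ <- waveform(rnorm(8000, sd = 0.03), 8000)
  d_ <- waveform(rnorm(8000, sd = 0.07), 8000)
  m0 <- mix_at_snr(t_, d_, 0)
  s0 <- attr(m0, "target_scale")
  expect_equal(s0 * rms(t_), rms(d_), tolerance = 1e-6)
  m10 <- mix_at_snr(t_, d_, 10)
  s10 <- attr(m10, "target_scale")
  expect_equal(s10 * rms(t_) / rms(d_), 10^0.5, tolerance = 1e-6)
  expect_equal(rms(m0), 0.02, tolerance = 1e-12)
  expect_error(mix_at_snr(t_, waveform(numeric(8000), 8000), 0),
               class = "gainlisten_input_error")
})

test_that("bandpass augmentation triggers at its configured probability", {
  tk <- mk_talker(110)
  u <- synth_utterance(tk, "dune", 0.25, 8000, seed = 10, f_cap = 3000)
  set.seed(40)
  n <- 10000
  hits <- 0L
  for (i in seq_len(n)) {
    ua <- augment_signal(u, "bandpass", prob = 0.5,
                         low_range = c(40, 400), high_range = c(1000, 3000))
    if (!is.null(ua$augmentations$bandpass)) hits <- hits + 1L
  }
  ci <- stats::binom.test(hits, n, 0.5)$conf.int
  expect_true(0.5 >= ci[1] && 0.5 <= ci[2])
})

test_that("time shifts keep the labeled word over the material midpoint", {
  tk <- mk_talker(110)
  u <- synth_utterance(tk, c("dune", "ember", "frost"), 2.5, 2000, seed = 11,
                       f_cap = 900)
  set.seed(41)
  word_dur <- diff(u$word_boundaries[2, ])
  for (i in 1:200) {
    us <- augment_signal(u, "timeshift")
    b <- us$word_boundaries
    mid <- us$duration / 2
    expect_true(b[2, "start"] <= mid && b[2, "end"] >= mid)
    expect_lte(abs(us$augmentations$timeshift), 0.5 * word_dur + 1e-9)
  }
})

test_that("scene sampling matches its stated distributions", {
  config <- scene_config(talkers = toy_talkers(), vocabulary = toy_vocabulary(),
                         sample_rate = 2000, spatialize = "diotic",
                         f_cap = 900)
  set.seed(42)
  n <- 10000
  counts <- integer(6)
  colocated <- 0L
  silent <- 0L
  labels <- character(n)
  for (i in seq_len(n)) {
    s <- sample_scene_spec(config)
    counts[s$n_distractors] <- counts[s$n_distractors] + 1L
    if (s$co_located) colocated <- colocated + 1L
    if (s$silence_cue) silent <- silent + 1L
    labels[i] <- s$label
    expect_true(s$n_speech <= s$n_distractors)
  }
  chi <- stats::chisq.test(counts, p = rep(1 / 6, 6))
  expect_gt(chi$p.value, 0.01)
  expect_lt(abs(colocated / n - 0.5), 0.015)
  expect_lt(abs(silent / n - 0.1), 0.01)
  # labels cover the vocabulary roughly uniformly
  expect_equal(length(unique(labels)), 8)
})

test_that("realized scenes have co-located cue and target", {
  set.seed(43)
  config <- scene_config(talkers = toy_talkers(), vocabulary = toy_vocabulary(),
                         sample_rate = 2000, f_cap = 900,
                         spatialize = "binaural", keep_components = TRUE,
                         silence_cue_prob = 0, timeshift = FALSE,
                         bandpass_prob = 0)
  sc <- assemble_scene(config, seed = 44)
  # the cue is rendered at the target's location: re-render its mono
  # waveform there and compare
  re_cue <- normalize_rms(
    render_binaural(sc$cue_utterance$waveform, sc$spec$target_location),
    0.02
  )
  expect_equal(sc$cue$samples, re_cue$samples, tolerance = 1e-9)
})

test_that("silence-cue scenes are single-talker with an all-zero cue", {
  config <- scene_config(talkers = toy_talkers(), vocabulary = toy_vocabulary(),
                         sample_rate = 2000, f_cap = 900,
                         spatialize = "diotic", silence_cue_prob = 1,
                         keep_components = TRUE)
  sc <- assemble_scene(config, seed = 45)
  expect_true(all(sc$cue$samples == 0))
  expect_equal(length(sc$components$distractors), 0)
  expect_equal(rms(sc$mixture), 0.02, tolerance = 1e-12)
})

test_that("mixtures are the sample-wise sum of their components pre-normalization", {
  config <- scene_config(talkers = toy_talkers(), vocabulary = toy_vocabulary(),
                         sample_rate = 2000, f_cap = 900,
                         spatialize = "diotic", silence_cue_prob = 0,
                         keep_components = TRUE)
  sc <- assemble_scene(config, seed = 46)
  scale <- attr(sc$mixture, "target_scale")
  prenorm <- attr(sc$mixture, "prenorm_rms")
  dist_sum <- Reduce(`+`, lapply(sc$components$distractors, function(d) d$samples))
  recon <- (scale * sc$components$target$samples + dist_sum) * (0.02 / prenorm)
  expect_equal(sc$mixture$samples, recon, tolerance = 1e-10)
  expect_equal(rms(sc$mixture), 0.02, tolerance = 1e-12)
})

test_that("scenes are reproducible from (config, seed)", {
  config <- toy_scene_config()
  s1 <- assemble_scene(config, seed = 47)
  s2 <- assemble_scene(config, seed = 47)
  expect_identical(s1$mixture$samples, s2$mixture$samples)
  expect_identical(s1$cue$samples, s2$cue$samples)
  expect_identical(s1$label, s2$label)
})

test_that("every scene's label is the word over the material midpoint", {
  config <- toy_scene_config()
  set.seed(48)
  for (i in 1:25) {
    sc <- realize_scene(sample_scene_spec(config), config)
    u <- sc$target_utterance
    expect_equal(u$word_sequence[middle_word_index(u)], sc$label)
  }
})

test_that("balance_corpus caps, fills quotas, and equalizes groups", {
  ex <- data.frame(
    class = c(rep("a", 7), rep("b", 3)),
    group = c(rep("f", 5), rep("m", 5)),
    id = 1:10
  )
  set.seed(49)
  out <- balance_corpus(ex, max_per_class = 5, quota = 5)
  expect_equal(unname(table(out$class)["a"]), 5L)
  expect_equal(unname(table(out$class)["b"]), 5L)
  out2 <- balance_corpus(ex, max_per_class = 5, quota = 5, group_key = "group")
  tg <- table(out2$group)
  expect_equal(unname(tg[1]), unname(tg[2]))
  # deterministic under a fixed seed
  set.seed(50); o1 <- balance_corpus(ex, 5, 5, group_key = "group")
  set.seed(50); o2 <- balance_corpus(ex, 5, 5, group_key = "group")
  expect_identical(o1, o2)
  # empty classes are reported and excluded
  expect_warning(balance_corpus(ex, 5, classes = c("a", "b", "zz")),
                 "zero examples")
})

test_that("word signatures are distinct across the toy vocabulary", {
  sigs <- lapply(toy_vocabulary(), word_signature)
  rates <- vapply(sigs, `[[`, numeric(1), "am_rate")
  bumps <- vapply(sigs, `[[`, numeric(1), "bump_frac")
  expect_equal(length(unique(paste(rates, bumps))), 8)
})

test_that("scene manifests round-trip through JSON", {
  config <- toy_scene_config()
  scenes <- lapply(61:63, function(s) assemble_scene(config, seed = s))
  path <- tempfile(fileext = ".json")
  write_scene_manifest(scenes, path)
  m <- read_scene_manifest(path)
  expect_equal(length(m), 3)
  expect_equal(m[[2]]$label, scenes[[2]]$label)
  expect_equal(unlist(m[[1]]$target_words), scenes[[1]]$target_words)
  expect_equal(m[[3]]$snr, scenes[[3]]$spec$snr)
  unlink(path)
})

test_that("WAV files round-trip through read/write", {
  set.seed(51)
  w <- waveform(matrix(runif(2 * 400, -0.5, 0.5), 2), 8000)
  p1 <- tempfile(fileext = ".wav")
  write_wav(w, p1, format = "float32")
  r1 <- read_wav(p1)
  expect_equal(r1$sample_rate, 8000)
  expect_equal(r1$samples, w$samples, tolerance = 1e-7)
  p2 <- tempfile(fileext = ".wav")
  write_wav(w, p2, format = "pcm16")
  r2 <- read_wav(p2)
  expect_equal(r2$samples, w$samples, tolerance = 1e-4)
  unlink(c(p1, p2))
})
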