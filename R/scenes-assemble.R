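# Full cocktail-party scene assembly.
#
# A scene is one labeled training/evaluation exemplar: a cue clip (the
# target talker alone, at the target's location), and a mixture of the
# target with 1-6 distractor sources at sampled levels, locations and SNR.
# Sampling of the scene's discrete decisions (sample_scene_spec) is
# separated from signal realization (realize_scene) so distributional
# properties of the sampler can be audited cheaply.

#' Scene-generation configuration
#'
#' Defaults implement the reference training-scene distribution: 1-6
#' distractors, a uniform speech/non-speech split, source levels uniform in
#' 50-70 dB SPL, SNR uniform in -10..10 dB, 50% co-located distractors,
#' 10% silence-cue single-talker examples, bandpass augmentation of cue or
#' target with probability 0.5, word-preserving time shifts, and RMS 0.02
#' normalization of cue and mixture.
#'
#' @param talkers list of `talker_spec`.
#' @param vocabulary character vector of word labels.
#' @param sample_rate audio rate, Hz.
#' @param material_duration source-clip duration, s (the cochlear stage
#'   later excerpts the middle `excerpt` seconds).
#' @param excerpt excerpt duration used downstream, s.
#' @param words_per_utterance words tiling each utterance.
#' @param n_distractor_range inclusive range of distractor counts.
#' @param speech_only force all distractors to be talkers.
#' @param level_range distractor level range, dB SPL.
#' @param snr_range SNR range, dB.
#' @param colocate_prob probability that all distractors share the target's
#'   location.
#' @param silence_cue_prob fraction of single-talker, silent-cue examples.
#' @param bandpass_prob bandpass-augmentation probability.
#' @param timeshift apply word-preserving time shifts to the target.
#' @param spatialize `"binaural"` (parametric rendering over a sampled
#'   room/grid) or `"diotic"`.
#' @param nonspeech_kinds noise kinds for non-speech distractors.
#' @param mixture_rms RMS of the normalized cue and mixture.
#' @param f_cap component frequency cap for synthesis, Hz.
#' @param room optional fixed `room_spec` (sampled per scene if `NULL`).
#' @param grid optional fixed location grid (built per scene if `NULL`).
#' @param keep_components retain pre-normalization component renders on
#'   each realized scene (linearity audit trail).
#' @return list of class `scene_config`.
#' @export
scene_config <- function(talkers, vocabulary,
                         sample_rate = 44100, material_duration = 2.5,
                         excerpt = 2, words_per_utterance = 3,
                         n_distractor_range = c(1L, 6L),
                         speech_only = FALSE,
                         level_range = c(50, 70), snr_range = c(-10, 10),
                         colocate_prob = 0.5, silence_cue_prob = 0.1,
                         bandpass_prob = 0.5, timeshift = TRUE,
                         spatialize = c("binaural", "diotic"),
                         nonspeech_kinds = c("pink", "speech-shaped"),
                         mixture_rms = 0.02, f_cap = NULL,
                         room = NULL, grid = NULL,
                         keep_components = FALSE) {
  spatialize <- match.arg(spatialize)
  if (length(talkers) < 2) stop_config("need at least two talkers")
  if (length(vocabulary) < 2) stop_config("need at least two words")
  structure(as.list(environment()), class = "scene_config")
}

#' Sample the discrete decisions of one scene
#'
#' Runs the scene-sampling procedure without synthesizing audio: target
#' talker and words, cue words (same talker, different middle word),
#' distractor count, speech/non-speech split, distractor draws (talkers
#' other than the target; middle words differing from the label), levels,
#' SNR, the co-location flag and source locations, and the silence-cue
#' flag. Uses R's global RNG.
#'
#' @param config `scene_config`.
#' @return list of class `scene_spec` recording every decision.
#' @export
sample_scene_spec <- function(config) {
  vocab <- config$vocabulary
  wpu <- config$words_per_utterance
  mid <- (wpu + 1L) %/% 2L
  pick_words <- function(exclude_mid = NULL) {
    w <- sample(vocab, wpu, replace = length(vocab) < wpu + 1)
    if (!is.null(exclude_mid) && w[mid] %in% exclude_mid) {
      w[mid] <- sample(setdiff(vocab, exclude_mid), 1)
    }
    w
  }
  t_idx <- sample(seq_along(config$talkers), 1)
  target_words <- pick_words()
  label <- target_words[mid]
  cue_words <- pick_words(exclude_mid = label)
  silence_cue <- stats::runif(1) < config$silence_cue_prob
  n_d <- sample(config$n_distractor_range[1]:config$n_distractor_range[2], 1)
  n_speech <- if (config$speech_only) n_d else sample(0:n_d, 1)
  other <- setdiff(seq_along(config$talkers), t_idx)
  distractors <- vector("list", n_d)
  for (j in seq_len(n_d)) {
    if (j <= n_speech) {
      d_idx <- if (length(other) == 1) other else sample(other, 1)
      distractors[[j]] <- list(
        type = "speech", talker = d_idx,
        words = pick_words(exclude_mid = label)
      )
    } else {
      distractors[[j]] <- list(
        type = "nonspeech",
        kind = if (length(config$nonspeech_kinds) == 1) {
          config$nonspeech_kinds
        } else sample(config$nonspeech_kinds, 1)
      )
    }
    distractors[[j]]$level <- stats::runif(1, config$level_range[1],
                                           config$level_range[2])
  }
  co_located <- stats::runif(1) < config$colocate_prob
  target_loc <- NULL
  room <- NULL
  if (config$spatialize == "binaural") {
    room <- config$room %||% sample_room_and_listener()
    grid <- config$grid %||% build_location_grid(room)
    gi <- sample(nrow(grid), 1)
    target_loc <- source_location(grid$azimuth[gi], grid$elevation[gi],
                                  grid$distance[gi])
    for (j in seq_len(n_d)) {
      if (co_located) {
        distractors[[j]]$location <- target_loc
      } else {
        gj <- sample(nrow(grid), 1)
        distractors[[j]]$location <-
          source_location(grid$azimuth[gj], grid$elevation[gj],
                          grid$distance[gj])
      }
    }
  }
  structure(
    list(
      target_talker = t_idx, target_words = target_words, label = label,
      cue_words = cue_words, silence_cue = silence_cue,
      n_distractors = n_d, n_speech = n_speech, distractors = distractors,
      snr = stats::runif(1, config$snr_range[1], config$snr_range[2]),
      co_located = co_located, target_location = target_loc, room = room
    ),
    class = "scene_spec"
  )
}

# render a mono source according to the scene's spatialization mode
spatialize_source <- function(w, loc, config) {
  if (config$spatialize == "diotic" || is.null(loc)) diotic(w)
  else render_binaural(w, loc)
}

#' Realize a sampled scene as audio
#'
#' Synthesizes target, cue and distractor signals, applies augmentations,
#' sets distractor levels, spatializes all sources (or presents them
#' diotically), mixes at the sampled SNR and RMS-normalizes cue and
#' mixture. Silence-cue scenes contain the target alone with an all-zero
#' cue.
#'
#' @param sspec `scene_spec`.
#' @param config `scene_config`.
#' @return list of class `scene` with `spec`, `cue` and `mixture` (stereo
#'   `waveform`s), `label`, `target_words`, `distractor_words`, and, when
#'   `config$keep_components`, the pre-normalization component renders.
#' @export
realize_scene <- function(sspec, config) {
  fs <- config$sample_rate
  dur <- config$material_duration
  tk <- config$talkers[[sspec$target_talker]]
  target <- synth_utterance(tk, sspec$target_words, dur, fs,
                            f_cap = config$f_cap)
  if (config$timeshift) target <- augment_signal(target, "timeshift")
  cue_utt <- synth_utterance(tk, sspec$cue_words, dur, fs,
                             f_cap = config$f_cap)
  if (config$bandpass_prob > 0 && stats::runif(1) < config$bandpass_prob) {
    # the bandpass hits either the cue or the target, equiprobably
    if (stats::runif(1) < 0.5) {
      cue_utt <- augment_signal(cue_utt, "bandpass", prob = 1)
    } else {
      target <- augment_signal(target, "bandpass", prob = 1)
    }
  }
  target_r <- spatialize_source(target$waveform, sspec$target_location, config)
  cue_r <- spatialize_source(cue_utt$waveform, sspec$target_location, config)
  distractor_words <- character(0)
  if (sspec$silence_cue) {
    mixture <- normalize_rms(target_r, config$mixture_rms)
    cue <- waveform(matrix(0, 2, ncol(target_r$samples)), fs)
    components <- list(target = target_r, distractors = list())
  } else {
    renders <- vector("list", sspec$n_distractors)
    for (j in seq_len(sspec$n_distractors)) {
      d <- sspec$distractors[[j]]
      if (d$type == "speech") {
        du <- synth_utterance(config$talkers[[d$talker]], d$words, dur, fs,
                              f_cap = config$f_cap)
        # distractor clips get the same word-preserving time-shift
        # distribution as targets, so temporal alignment never identifies
        # the target stream
        if (config$timeshift) du <- augment_signal(du, "timeshift")
        distractor_words <- union(distractor_words, du$word_sequence)
        src <- du$waveform
      } else {
        src <- shaped_noise(d$kind,
                            reference = if (d$kind == "speech-shaped") {
                              target$waveform
                            } else NULL,
                            duration = dur, sample_rate = fs)
      }
      src <- set_level(src, d$level)
      renders[[j]] <- spatialize_source(src, d$location, config)
    }
    dist_sum <- renders[[1]]
    if (sspec$n_distractors > 1) {
      acc <- dist_sum$samples
      for (j in 2:sspec$n_distractors) acc <- acc + renders[[j]]$samples
      dist_sum <- waveform(acc, fs)
    }
    mixture <- mix_at_snr(target_r, dist_sum, sspec$snr,
                          normalize_rms = config$mixture_rms)
    cue <- normalize_rms(cue_r, config$mixture_rms)
    components <- list(target = target_r, distractors = renders)
  }
  out <- list(
    spec = sspec, cue = cue, mixture = mixture, label = sspec$label,
    target_words = target$word_sequence,
    distractor_words = distractor_words,
    target_utterance = target, cue_utterance = if (sspec$silence_cue) NULL else cue_utt
  )
  if (config$keep_components) out$components <- components
  structure(out, class = "scene")
}

#' Sample and realize one scene
#'
#' @param config `scene_config`.
#' @param seed optional integer seed; the scene is fully reproducible from
#'   (config, seed).
#' @return realized `scene` (see [realize_scene()]).
#' @export
assemble_scene <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  realize_scene(sample_scene_spec(config), config)
}

#' Write / read a JSON manifest of realized scenes
#'
#' The manifest records each scene's provenance (label, transcripts,
#' talker, distractor descriptors, SNR, locations, flags) without the
#' audio, so datasets stored as WAV directories can be re-joined with
#' their annotations.
#'
#' @param scenes list of realized `scene`s.
#' @param path output JSON path.
#' @return `path`, invisibly (`read_scene_manifest` returns a list).
#' @export
write_scene_manifest <- function(scenes, path) {
  entries <- lapply(seq_along(scenes), function(i) {
    sc <- scenes[[i]]
    sp <- sc$spec
    list(
      id = i, label = sc$label,
      target_words = sc$target_words,
      distractor_words = sc$distractor_words,
      target_talker = sp$target_talker,
      cue_words = sp$cue_words,
      silence_cue = sp$silence_cue,
      n_distractors = sp$n_distractors,
      n_speech = sp$n_speech,
      snr = sp$snr,
      co_located = sp$co_located,
      target_location = if (is.null(sp$target_location)) NULL else {
        unclass(sp$target_location)
      },
      distractors = lapply(sp$distractors, function(d) {
        d$location <- if (is.null(d$location)) NULL else unclass(d$location)
        d
      })
    )
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_scene_manifest
#' @export
read_scene_manifest <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Balance a labeled corpus
#'
#' Caps each class at `max_per_class` examples, upsamples every class with
#' replacement to `quota` examples, then (optionally) equalizes a grouping
#' key by downsampling the majority group(s) to the minimum group count.
#' Classes with zero examples are reported and excluded.
#'
#' @param examples data.frame with a `class` column (and the grouping
#'   column, if used).
#' @param max_per_class per-class cap.
#' @param quota per-class count after resampling (default `max_per_class`).
#' @param group_key optional column name to equalize across groups.
#' @param classes optional full class list (to report empty classes).
#' @return balanced data.frame.
#' @export
balance_corpus <- function(examples, max_per_class,
                           quota = max_per_class, group_key = NULL,
                           classes = NULL) {
  if (nrow(examples) == 0) stop_input("empty corpus")
  if (!is.null(classes)) {
    missing_cls <- setdiff(classes, unique(examples$class))
    if (length(missing_cls)) {
      warning("classes with zero examples excluded: ",
              paste(missing_cls, collapse = ", "))
    }
  }
  parts <- split(seq_len(nrow(examples)), examples$class)
  picked <- unlist(lapply(parts, function(idx) {
    if (length(idx) > max_per_class) idx <- sample(idx, max_per_class)
    if (length(idx) < quota) {
      c(idx, sample(idx, quota - length(idx), replace = TRUE))
    } else if (length(idx) > quota) {
      sample(idx, quota)
    } else idx
  }), use.names = FALSE)
  out <- examples[picked, , drop = FALSE]
  if (!is.null(group_key)) {
    gs <- split(seq_len(nrow(out)), out[[group_key]])
    m <- min(vapply(gs, length, integer(1)))
    keep <- unlist(lapply(gs, function(idx) {
      if (length(idx) > m) sample(idx, m) else idx
    }), use.names = FALSE)
    out <- out[sort(keep), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
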