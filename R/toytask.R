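# Desk-scale ("toy") study conditions: an 8-word vocabulary, two synthetic
# talkers with widely separated f0, diotic presentation at 0 dB SNR, and a
# small two-block network over a compact cochleagram. These are the fixed
# conditions under which the package's training and representational
# analyses are exercised; all sizes are configurable but the defaults
# below define the reference toy study.

#' Toy study vocabulary
#'
#' Eight word labels whose hashed modulation signatures are pairwise
#' distinct in AM rate, so the words are acoustically separable.
#'
#' @return character vector of 8 words.
#' @export
toy_vocabulary <- function() {
  c("arbor", "breeze", "cinder", "dune", "ember", "frost", "grove", "harbor")
}

#' Toy talker pair
#'
#' One talker per sex class with fixed, well-separated fundamentals
#' (110 Hz and 250 Hz) and fixed spectral envelopes, giving the cue-driven
#' gains a clean spectral handle on talker identity.
#'
#' @return list of two `talker_spec`s.
#' @export
toy_talkers <- function() {
  list(
    talker_spec("A01", "A", 110,
                list(tilt = 0.5, bump_center = c(400, 700),
                     bump_amp = c(1.5, 1.0), bump_bw = c(120, 200))),
    talker_spec("B01", "B", 250,
                list(tilt = 0.5, bump_center = c(500, 800),
                     bump_amp = c(1.2, 1.4), bump_bw = c(150, 220)))
  )
}

#' Toy cochlear configuration
#'
#' A compact front-end for 2 kHz audio: 16 gammatone channels between 50
#' and 900 Hz, cochleagram frame rate 50 Hz, middle 2 s of 2.5 s material
#' (a 2 x 16 x 100 network input).
#'
#' @return list with `sample_rate`, `filterbank`, `out_rate`, `excerpt`,
#'   `resample_width`.
#' @export
toy_cochlear_config <- function() {
  list(
    sample_rate = 2000,
    filterbank = make_filterbank(16, 50, 900, sample_rate = 2000),
    out_rate = 50, excerpt = 2, resample_width = 16
  )
}

#' Cochleagram under a cochlear configuration
#'
#' @param w `waveform` (mono input is presented diotically).
#' @param cc configuration from [toy_cochlear_config()] (or the same shape
#'   with other values).
#' @return `cochleagram`.
#' @export
apply_cochlear <- function(w, cc) {
  cochleagram(diotic(w), cc$filterbank, out_rate = cc$out_rate,
              excerpt = cc$excerpt, resample_width = cc$resample_width)
}

#' Toy scene configuration
#'
#' Two talkers, eight words, one speech distractor (the other talker),
#' diotic presentation, 0 dB SNR, 10% silence-cue single-talker examples,
#' word-preserving time shifts, RMS 0.02 normalization. Bandpass
#' augmentation is disabled (its 4-16 kHz cutoff range is above the toy
#' audio bandwidth).
#'
#' @return `scene_config`.
#' @export
toy_scene_config <- function() {
  scene_config(
    talkers = toy_talkers(), vocabulary = toy_vocabulary(),
    sample_rate = 2000, material_duration = 2.5, words_per_utterance = 3,
    n_distractor_range = c(1L, 1L), speech_only = TRUE,
    snr_range = c(0, 0), silence_cue_prob = 0.1,
    bandpass_prob = 0, timeshift = TRUE, spatialize = "diotic",
    f_cap = 900
  )
}

#' Toy network architecture
#'
#' Two convolutional blocks (16 and 32 channels) over the 2 x 16 x 100 toy
#' cochleagram, a 64-unit fully-connected layer and an 8-way softmax.
#'
#' @param variant network variant (see [network_spec()]).
#' @return `network_spec`.
#' @export
toy_network_spec <- function(variant = "feature-gain") {
  network_spec(
    input_dim = c(if (variant == "baseline") 4L else 2L, 16L, 100L),
    blocks = list(
      list(c_out = 16L, n_f = 5L, n_t = 9L, pool_f = 2L, pool_t = 4L),
      list(c_out = 32L, n_f = 3L, n_t = 5L, pool_f = 2L, pool_t = 2L)
    ),
    fc_width = 64L, n_classes = 8L, dropout_p = 0.5, variant = variant
  )
}

#' Toy training configuration
#'
#' AdamW with a desk-scale learning rate and batch size; the epoch budget
#' and early-stopping patience keep a 2,000-scene run in the minutes
#' range on one CPU.
#'
#' @param seed training seed.
#' @param max_epochs epoch budget.
#' @return `train_config`.
#' @export
toy_train_config <- function(seed = 1, max_epochs = 20) {
  train_config(learning_rate = 2e-3, batch_size = 32, weight_decay = 1e-4,
               max_epochs = max_epochs, seed = seed, patience = 6)
}

#' Generate labeled toy scenes with cochleagrams
#'
#' Samples and realizes scenes from [toy_scene_config()] and converts cue
#' and mixture to cochleagrams. With `with_components`, each example also
#' carries the target-alone and distractor-alone cochleagrams (each
#' RMS-normalized to 0.02 before the cochlear stage) and a "swap cue": an
#' utterance by the distractor talker, for cue-swap evaluations. Silence-
#' cue scenes are excluded when components are requested (they have no
#' distractor).
#'
#' @param n number of scenes.
#' @param seed integer seed; the dataset is reproducible from it.
#' @param with_components build component cochleagrams and swap cues.
#' @param config optional `scene_config` override.
#' @param cc optional cochlear configuration override.
#' @return list of examples with fields `cue`, `mixture`, `label` (class
#'   index), `label_word`, `target_words`, `distractor_words`,
#'   `distractor_label`, `silence_cue`, and optionally `target`,
#'   `distractor`, `swap_cue`.
#' @export
generate_toy_scenes <- function(n, seed = 1, with_components = FALSE,
                                config = NULL, cc = NULL) {
  set.seed(seed)
  config <- config %||% toy_scene_config()
  if (with_components) config$keep_components <- TRUE
  cc <- cc %||% toy_cochlear_config()
  vocab <- config$vocabulary
  out <- vector("list", n)
  i <- 0L
  while (i < n) {
    sc <- realize_scene(sample_scene_spec(config), config)
    if (with_components && sc$spec$silence_cue) next
    i <- i + 1L
    ex <- list(
      cue = apply_cochlear(sc$cue, cc),
      mixture = apply_cochlear(sc$mixture, cc),
      label = match(sc$label, vocab),
      label_word = sc$label,
      target_words = sc$target_words,
      distractor_words = sc$distractor_words,
      silence_cue = sc$spec$silence_cue
    )
    if (with_components) {
      d <- sc$spec$distractors[[1]]
      mid <- (config$words_per_utterance + 1L) %/% 2L
      ex$distractor_label <- d$words[mid]
      tk_d <- config$talkers[[d$talker]]
      # isolated sources: the very renders that entered the mixture,
      # normalized to the evaluation RMS
      ex$target <- apply_cochlear(
        normalize_rms(sc$components$target, config$mixture_rms), cc)
      ex$distractor <- apply_cochlear(
        normalize_rms(sc$components$distractors[[1]], config$mixture_rms), cc)
      # cue-swap: a different excerpt of the distractor talker
      swap_words <- vocab[sample.int(length(vocab), config$words_per_utterance)]
      mid <- (config$words_per_utterance + 1L) %/% 2L
      if (swap_words[mid] == ex$distractor_label) {
        swap_words[mid] <- sample(setdiff(vocab, ex$distractor_label), 1)
      }
      su <- synth_utterance(tk_d, swap_words, config$material_duration,
                            config$sample_rate, f_cap = config$f_cap)
      ex$swap_cue <- apply_cochlear(
        normalize_rms(su$waveform, config$mixture_rms), cc)
    }
    out[[i]] <- ex
  }
  out
}

#' Run the reference toy study
#'
#' Trains a feature-gain network on `n_train` toy scenes, then measures:
#' cued word-recognition accuracy on held-out scenes (with a binomial test
#' against 1/8 chance), target- and distractor-word report rates under
#' cue swap (the cue replaced by an excerpt of the distractor talker),
#' and locus-of-selection profiles for the trained network and a
#' random-weight control.
#'
#' The feature-gain network is trained from a symmetry-broken
#' initialization (`theta1 = 0.8`): with exact identity gains the two
#' equivalent attention solutions (suppressing non-cue features vs
#' amplifying them) are equally reachable, and a mild initial bias toward
#' pass-through attention steers optimization into the canonical
#' suppression regime.
#'
#' @param seed master seed; dataset, initialization and training seeds are
#'   derived from it.
#' @param n_train,n_val,n_eval,n_profile problem sizes.
#' @param max_epochs training epoch budget.
#' @param verbose print training progress.
#' @return list with the trained network and all measured quantities.
#' @export
run_toy_study <- function(seed = 1, n_train = 2000, n_val = 200,
                          n_eval = 300, n_profile = 150, max_epochs = 20,
                          verbose = FALSE) {
  train_data <- generate_toy_scenes(n_train, seed = seed)
  val_data <- generate_toy_scenes(n_val, seed = seed + 1000L)
  eval_data <- generate_toy_scenes(n_eval, seed = seed + 2000L,
                                   with_components = TRUE)
  gi <- list(c(0.8, 60, 0.07), c(0.8, 5, 0.5), c(0.8, 5, 0.5))
  net <- init_network(toy_network_spec(), seed = seed + 3000L,
                      gain_init = gi)
  random_net <- init_network(toy_network_spec(), seed = seed + 4000L)
  fit <- train_model(net, train_data, toy_train_config(seed = seed + 5000L,
                                                       max_epochs = max_epochs),
                     val_data = val_data, verbose = verbose)
  net <- fit$net
  vocab <- toy_vocabulary()
  responses <- vapply(eval_data, function(ex) {
    which.max(attended_forward(ex$cue, ex$mixture, net))
  }, integer(1))
  labels <- vapply(eval_data, `[[`, integer(1), "label")
  accuracy <- mean(responses == labels)
  btest <- stats::binom.test(sum(responses == labels), length(labels),
                             p = 1 / 8, alternative = "greater")
  # cue swap: attend to the distractor talker instead
  swap_responses <- vapply(eval_data, function(ex) {
    which.max(attended_forward(ex$swap_cue, ex$mixture, net))
  }, integer(1))
  dist_labels <- vapply(eval_data, function(ex) {
    match(ex$distractor_label, vocab)
  }, integer(1))
  swap_target_rate <- mean(swap_responses == labels)
  swap_distractor_rate <- mean(swap_responses == dist_labels)
  prof_trials <- lapply(eval_data[seq_len(min(n_profile, length(eval_data)))],
                        function(ex) {
    list(cue = ex$cue, target = ex$target, distractor = ex$distractor,
         mixture = ex$mixture)
  })
  profile_trained <- selection_profile(net, prof_trials, snr = 0)
  profile_random <- selection_profile(random_net, prof_trials, snr = 0)
  # per-trial increase in the target-minus-distractor correlation gap from
  # the cochleagram stage to the final stage
  gap_increase <- function(prof) {
    ct <- attr(prof, "target_by_trial")
    cd <- attr(prof, "distractor_by_trial")
    last <- ncol(ct)
    (ct[, last] - cd[, last]) - (ct[, 1] - cd[, 1])
  }
  gi_t <- gap_increase(profile_trained)
  gi_r <- gap_increase(profile_random)
  list(
    net = net, random_net = random_net, fit = fit,
    accuracy = accuracy, n_eval = length(labels), chance = 1 / 8,
    binom_p = btest$p.value,
    swap_target_rate = swap_target_rate,
    swap_distractor_rate = swap_distractor_rate,
    profile_trained = profile_trained,
    profile_random = profile_random,
    gap_increase_trained = mean(gi_t),
    gap_increase_trained_p =
      stats::t.test(gi_t, alternative = "greater")$p.value,
    gap_increase_random = mean(gi_r),
    gap_increase_random_p = stats::t.test(gi_r)$p.value
  )
}
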