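# Desk-scale optimization and evaluation harness.
#
# Parameters are flattened to a single numeric vector for the optimizer
# (depth-first traversal of the parameter tree, matching unlist()).

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(vec, template) {
  pos <- 0L
  walk <- function(t) {
    if (is.list(t)) return(lapply(t, walk))
    n <- length(t)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(t))) dim(out) <- dim(t)
    out
  }
  walk(template)
}

# weight decay applies only to convolution kernels and fully-connected
# weight matrices, never to normalization, bias, or gain parameters
decay_mask <- function(params) {
  tpl <- list(
    blocks = lapply(params$blocks, function(b) {
      list(W = array(1, dim(b$W)), gamma = 0 * b$gamma, beta = 0 * b$beta)
    }),
    fc1 = list(W = matrix(1, nrow(params$fc1$W), ncol(params$fc1$W)),
               b = numeric(length(params$fc1$b))),
    fc2 = list(W = matrix(1, nrow(params$fc2$W), ncol(params$fc2$W)),
               b = numeric(length(params$fc2$b))),
    gains = lapply(params$gains, function(g) c(0, 0, 0))
  )
  flatten_params(tpl)
}

#' Training configuration
#'
#' Defaults follow the reference optimization recipe (AdamW, learning rate
#' 5e-5, batch size 288, dropout 0.5); desk-scale runs typically override
#' the learning rate, batch size and epoch budget.
#'
#' @param learning_rate AdamW learning rate (> 0).
#' @param batch_size minibatch size.
#' @param optimizer only `"adamw"` is provided.
#' @param weight_decay decoupled weight decay on convolution and
#'   fully-connected weights.
#' @param max_epochs epoch budget.
#' @param seed integer seed controlling shuffling and dropout.
#' @param dropout_p dropout probability (stored on the network spec).
#' @param patience epochs without validation improvement before stopping.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-5, batch_size = 288,
                         optimizer = "adamw", weight_decay = 0.01,
                         max_epochs = 30, seed = 1, dropout_p = 0.5,
                         patience = 3) {
  if (learning_rate <= 0) stop_config("learning_rate must be positive")
  if (!identical(optimizer, "adamw")) stop_config("unsupported optimizer")
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 optimizer = optimizer, weight_decay = weight_decay,
                 max_epochs = max_epochs, seed = as.integer(seed),
                 dropout_p = dropout_p, patience = patience),
            class = "train_config")
}

#' Train a network on cued word-recognition examples
#'
#' Minimizes softmax cross-entropy on the middle-word label with AdamW.
#' Gain parameters and block weights are optimized jointly; the cochlear
#' front-end is outside the network and is never modified. Training stops
#' early when validation accuracy fails to improve for `cfg$patience`
#' consecutive epochs.
#'
#' @param net `gain_network`.
#' @param data list of examples, each a list with `cue`, `mixture`
#'   (cochleagrams or activation arrays) and `label` (1-based class index).
#' @param cfg `train_config`.
#' @param val_data optional validation examples in the same format.
#' @param verbose print per-epoch progress.
#' @return list with the trained `net`, per-batch `loss_trace`, per-epoch
#'   `val_accuracy`, and `epochs_run`.
#' @export
train_model <- function(net, data, cfg, val_data = NULL, verbose = FALSE) {
  set.seed(cfg$seed)
  theta <- flatten_params(net$params)
  template <- net$params
  wd_mask <- decay_mask(net$params)
  mom <- numeric(length(theta))
  vel <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- length(data)
  loss_trace <- numeric(0)
  val_acc <- numeric(0)
  best_val <- -Inf
  stall <- 0L
  epochs_run <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + cfg$batch_size - 1, n)]
      gsum <- numeric(length(theta))
      lsum <- 0
      for (i in idx) {
        ex <- data[[i]]
        fwd <- forward_full(net, ex$cue, ex$mixture, train_mode = TRUE,
                            keep_cache = TRUE)
        p_lab <- fwd$probs[ex$label]
        lsum <- lsum + (-log(max(p_lab, 1e-12)))
        g <- net_backward(net, fwd, ex$label)
        gsum <- gsum + flatten_params(g)
      }
      gbar <- gsum / length(idx)
      lbar <- lsum / length(idx)
      if (!all(is.finite(gbar)) || !is.finite(lbar)) {
        stop("training diverged: non-finite loss or gradient at epoch ",
             epoch, ", step ", step + 1,
             " (mean loss ", signif(lbar, 4), ")")
      }
      step <- step + 1L
      mom <- b1 * mom + (1 - b1) * gbar
      vel <- b2 * vel + (1 - b2) * gbar^2
      mhat <- mom / (1 - b1^step)
      vhat <- vel / (1 - b2^step)
      theta <- theta - cfg$learning_rate *
        (mhat / (sqrt(vhat) + eps) + cfg$weight_decay * wd_mask * theta)
      net$params <- unflatten_params(theta, template)
      loss_trace <- c(loss_trace, lbar)
    }
    epochs_run <- epoch
    if (!is.null(val_data)) {
      acc <- mean(vapply(val_data, function(ex) {
        p <- forward_full(net, ex$cue, ex$mixture)$probs
        which.max(p) == ex$label
      }, logical(1)))
      val_acc <- c(val_acc, acc)
      if (verbose) {
        message(sprintf("epoch %d: train loss %.3f, val acc %.3f",
                        epoch, mean(tail(loss_trace, length(starts))), acc))
      }
      if (acc > best_val + 1e-9) {
        best_val <- acc
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    } else if (verbose) {
      message(sprintf("epoch %d: train loss %.3f", epoch,
                      mean(tail(loss_trace, length(starts)))))
    }
  }
  list(net = net, loss_trace = loss_trace, val_accuracy = val_acc,
       epochs_run = epochs_run)
}

#' Evaluate a frozen network on a list of trials
#'
#' Deterministic forward passes in evaluation mode (no dropout). The
#' response is the argmax class (ties broken toward the lowest index). If
#' trials carry `target_words` / `distractor_words` transcripts and a
#' vocabulary is supplied, correct/confusion flags are scored with
#' [score_response()]. Per-trial failures are recorded in the `error`
#' column and the run continues.
#'
#' @param net `gain_network`.
#' @param trials list of trials, each with `cue`, `mixture`, and optional
#'   `id`, `label`, `target_words`, `distractor_words`, `condition`.
#' @param vocabulary optional character vector mapping class indices to
#'   words.
#' @return data.frame with one row per trial (class `eval_result`); the
#'   full probability matrix is attached as attribute `"probabilities"`.
#' @export
evaluate_model <- function(net, trials, vocabulary = NULL) {
  n <- length(trials)
  probs <- matrix(NA_real_, n, net$spec$n_classes)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- trials[[i]]
    res <- tryCatch({
      p <- forward_full(net, tr$cue, tr$mixture)$probs
      probs[i, ] <- p
      ridx <- which.max(p)
      word <- if (!is.null(vocabulary)) vocabulary[ridx] else NA_character_
      correct <- NA
      confusion <- NA
      if (!is.null(vocabulary) && !is.null(tr$target_words)) {
        sc <- score_response(word, tr$target_words,
                             tr$distractor_words %||% character(0), vocabulary)
        correct <- sc["correct"]
        confusion <- sc["confusion"]
      } else if (!is.null(tr$label)) {
        correct <- ridx == tr$label
      }
      data.frame(
        id = tr$id %||% i, condition = tr$condition %||% NA_character_,
        response_index = ridx, response_word = word,
        correct = unname(correct), confusion = unname(confusion),
        max_prob = p[ridx], error = NA_character_,
        stringsAsFactors = FALSE
      )
    }, error = function(e) {
      data.frame(id = tr$id %||% i, condition = tr$condition %||% NA_character_,
                 response_index = NA_integer_, response_word = NA_character_,
                 correct = NA, confusion = NA, max_prob = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  attr(out, "probabilities") <- probs
  class(out) <- c("eval_result", class(out))
  out
}

#' Enumerate a factorial evaluation grid
#'
#' Builds the trial table for a condition-grid evaluation: every target
#' crossed with every distractor type and SNR, plus (optionally) one
#' no-distractor trial per target.
#'
#' @param n_targets number of target clips.
#' @param distractor_types character vector (or count) of distractor types.
#' @param snrs numeric vector of SNRs (dB).
#' @param include_no_distractor add one clean trial per target.
#' @return data.frame with columns `target`, `distractor_type`, `snr`.
#' @export
enumerate_trial_grid <- function(n_targets, distractor_types, snrs,
                                 include_no_distractor = TRUE) {
  if (length(distractor_types) == 1 && is.numeric(distractor_types)) {
    distractor_types <- paste0("distractor", seq_len(distractor_types))
  }
  g <- expand.grid(target = seq_len(n_targets),
                   distractor_type = distractor_types, snr = snrs,
                   stringsAsFactors = FALSE)
  if (include_no_distractor) {
    g <- rbind(g, data.frame(target = seq_len(n_targets),
                             distractor_type = "none", snr = Inf))
  }
  g
}
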