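# Network construction and the cue-gated forward pass.
#
# A gain network is a cascade of convolutional blocks over cochleagrams.
# The cue is propagated (ungated) with the same shared block weights as the
# mixture; at each gated stage the cue's time-averaged memory is squashed
# into a per-(channel, frequency) gain map that multiplies the mixture
# activation at every timepoint.

#' Network architecture specification
#'
#' @param input_dim input activation shape `c(channels, n_freq, n_time)`;
#'   2 channels for the gated variants, 4 for the `baseline` variant (the
#'   cue and mixture cochleagrams concatenated on the channel axis).
#' @param blocks list of block descriptors, each a list with `c_out`, `n_f`,
#'   `n_t`, and optional `pool_f`, `pool_t` (default 1).
#' @param fc_width width of the hidden fully-connected layer.
#' @param n_classes vocabulary size (>= 2).
#' @param dropout_p dropout probability in `[0, 1)` applied to the hidden
#'   fully-connected activations during training (default 0.5).
#' @param variant one of `"feature-gain"`, `"baseline"`, `"early-only"`,
#'   `"late-only"`.
#' @param gain_form gain parameterization (see [compute_gains()]).
#' @return object of class `network_spec` carrying the architecture and the
#'   derived per-stage activation shapes.
#' @export
network_spec <- function(input_dim, blocks, fc_width, n_classes,
                         dropout_p = 0.5,
                         variant = c("feature-gain", "baseline",
                                     "early-only", "late-only"),
                         gain_form = c("bounded", "printed")) {
  variant <- match.arg(variant)
  gain_form <- match.arg(gain_form)
  if (n_classes < 2) stop_config("n_classes must be >= 2")
  if (dropout_p < 0 || dropout_p >= 1) stop_config("dropout_p must be in [0, 1)")
  if (variant == "baseline" && input_dim[1] != 4) {
    stop_config("baseline variant takes 4 input channels ",
                "(cue and mixture concatenated)")
  }
  if (variant != "baseline" && input_dim[1] != 2) {
    stop_config("gated variants take 2 input channels")
  }
  shapes <- vector("list", length(blocks) + 1)
  shapes[[1]] <- as.integer(input_dim)
  cur <- as.integer(input_dim)
  for (l in seq_along(blocks)) {
    b <- blocks[[l]]
    b$pool_f <- b$pool_f %||% 1L
    b$pool_t <- b$pool_t %||% 1L
    blocks[[l]] <- b
    t_conv <- cur[3] - b$n_t + 1L
    if (t_conv < 1) stop_config("block ", l, ": time axis too short for kernel")
    cur <- c(b$c_out,
             if (b$pool_f > 1) cur[2] %/% b$pool_f else cur[2],
             if (b$pool_t > 1) t_conv %/% b$pool_t else t_conv)
    cur <- as.integer(cur)
    if (any(cur < 1)) stop_config("block ", l, ": activation collapsed to zero size")
    shapes[[l + 1]] <- cur
  }
  structure(
    list(input_dim = as.integer(input_dim), blocks = blocks,
         fc_width = as.integer(fc_width), n_classes = as.integer(n_classes),
         dropout_p = dropout_p, variant = variant, gain_form = gain_form,
         shapes = shapes, flat_dim = prod(cur)),
    class = "network_spec"
  )
}

# which stages (0 = cochleagram, l = after block l) receive gains
gated_stages <- function(spec) {
  L <- length(spec$blocks)
  switch(spec$variant,
    "feature-gain" = rep(TRUE, L + 1),
    "baseline"     = rep(FALSE, L + 1),
    "early-only"   = c(TRUE, rep(FALSE, L)),
    "late-only"    = c(rep(FALSE, L), TRUE)
  )
}

#' Initialize network parameters
#'
#' Convolution kernels use He initialization; layer-norm scales start at 1
#' and shifts at 0. Gain parameters start at identity attention
#' (`theta1 = 1`, so every gain is exactly 1 and the untrained network is
#' gain-free), with slope and threshold pre-set to the activation scale of
#' their stage: time-averaged compressed cochleagrams at the reference RMS
#' of 0.02 concentrate around 0.03-0.12 (hence `theta2 = 60`,
#' `theta3 = 0.07`), while rectified post-normalization block activations
#' average around 0.5 (hence `theta2 = 5`, `theta3 = 0.5`). This way the
#' sigmoid has usable contrast as soon as `theta1` moves off 1; the slope
#' and threshold remain learnable.
#'
#' @param spec `network_spec`.
#' @param seed optional integer seed for reproducible initialization.
#' @param gain_init initial `(theta1, theta2, theta3)`: a single vector for
#'   all gated stages, or a list with one vector per stage (cochleagram
#'   stage first). `NULL` selects the stage-matched defaults above.
#' @return object of class `gain_network` with fields `spec` and `params`.
#' @export
init_network <- function(spec, seed = NULL, gain_init = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(spec$blocks)
  blocks <- vector("list", L)
  for (l in seq_len(L)) {
    b <- spec$blocks[[l]]
    cin <- spec$shapes[[l]][1]
    fan_in <- cin * b$n_f * b$n_t
    blocks[[l]] <- list(
      W = array(stats::rnorm(b$c_out * fan_in, sd = sqrt(2 / fan_in)),
                c(b$c_out, cin, b$n_f, b$n_t)),
      gamma = array(1, spec$shapes[[l]]),
      beta = array(0, spec$shapes[[l]])
    )
  }
  D <- spec$flat_dim
  H <- spec$fc_width
  params <- list(
    blocks = blocks,
    fc1 = list(W = matrix(stats::rnorm(H * D, sd = sqrt(2 / D)), H, D),
               b = numeric(H)),
    fc2 = list(W = matrix(stats::rnorm(spec$n_classes * H, sd = sqrt(2 / H)),
                          spec$n_classes, H),
               b = numeric(spec$n_classes)),
    gains = if (is.null(gain_init)) {
      c(list(c(1, 60, 0.07)), rep(list(c(1, 5, 0.5)), L))
    } else if (is.list(gain_init)) {
      if (length(gain_init) != L + 1) {
        stop_config("gain_init list must have one entry per stage")
      }
      lapply(gain_init, as.numeric)
    } else {
      rep(list(as.numeric(gain_init)), L + 1)
    }
  )
  structure(list(spec = spec, params = params), class = "gain_network")
}

#' @export
print.gain_network <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<gain_network: %s, %d block(s), %d classes, input %s>\n",
              s$variant, length(s$blocks), s$n_classes,
              paste(s$input_dim, collapse = "x")))
  invisible(x)
}

as_activation <- function(x) {
  if (inherits(x, "cochleagram")) x$values else x
}

cat_channels <- function(a, b) {
  da <- dim(a)
  out <- array(0, c(da[1] + dim(b)[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# multiply activation [C,F,T] by gain map [C,F], broadcasting over time
apply_gain_map <- function(x, g) x * as.vector(g)

block_fwd_cache <- function(x, bp, keep = FALSE) {
  ln <- ln_fwd(x, bp$gamma, bp$beta)
  cv <- conv_fwd(ln$y, bp$W, keep = keep)
  r <- if (keep) cv$y else cv
  mask <- r > 0
  r[!mask] <- 0
  y <- pool_hanning(r, bp$s_f, bp$s_t)
  if (!keep) return(list(y = y))
  list(y = y, ln = ln, cv = cv, mask = mask, dim_relu = dim(mask),
       dimx = dim(x), bp = bp)
}

block_bwd <- function(cache, dy) {
  bp <- cache$bp
  dr <- pool_bwd(dy, cache$dim_relu, bp$s_f, bp$s_t)
  dr[!cache$mask] <- 0
  cb <- conv_bwd(cache$cv, bp$W, dr)
  lb <- ln_bwd(cache$ln, bp$gamma, cb$dx)
  list(dx = lb$dx, dW = cb$dW, dgamma = lb$dgamma, dbeta = lb$dbeta)
}

# the block parameter bundle used by the forward machinery
block_bundle <- function(net, l) {
  p <- net$params$blocks[[l]]
  s <- net$spec$blocks[[l]]
  list(W = p$W, gamma = p$gamma, beta = p$beta,
       s_f = s$pool_f, s_t = s$pool_t)
}

# Full forward pass for all variants. Returns probs, optional per-stage
# post-gain mixture activations (capture), and the caches needed for
# backprop (keep_cache).
forward_full <- function(net, cue, mix, train_mode = FALSE,
                         capture = FALSE, keep_cache = FALSE) {
  spec <- net$spec
  L <- length(spec$blocks)
  gated <- gated_stages(spec)
  cue_a <- as_activation(cue)
  mix_a <- as_activation(mix)
  baseline <- spec$variant == "baseline"
  if (!baseline && !identical(dim(cue_a), dim(mix_a))) {
    stop_input("cue and mixture activations must share shape")
  }
  if (baseline) {
    xm <- cat_channels(cue_a, mix_a)
    if (dim(xm)[1] != spec$input_dim[1]) {
      stop_config("baseline input channels do not match network spec")
    }
  } else {
    xm <- mix_a
    if (dim(xm)[1] != spec$input_dim[1]) {
      stop_input("activation channel count does not match network spec")
    }
  }
  # cue must be propagated up to the deepest gated stage
  top_gated <- if (any(gated)) max(which(gated)) - 1L else -1L
  stages <- if (capture) vector("list", L + 1) else NULL
  gcaches <- vector("list", L + 1)
  pre_gain <- vector("list", L + 1) # mixture activation before gain (gated stages)
  mix_caches <- vector("list", L)
  cue_caches <- vector("list", L)
  xc <- cue_a
  # stage 0
  if (gated[1]) {
    m0 <- time_average_memory(xc)
    gc0 <- gain_fwd(m0, net$params$gains[[1]], spec$gain_form)
    pre_gain[[1]] <- xm
    gcaches[[1]] <- gc0
    xm <- apply_gain_map(xm, gc0$g)
  }
  if (capture) stages[[1]] <- xm
  for (l in seq_len(L)) {
    bp <- block_bundle(net, l)
    bm <- block_fwd_cache(xm, bp, keep = keep_cache)
    xm <- bm$y
    if (keep_cache) mix_caches[[l]] <- bm
    if (!baseline && l <= top_gated) {
      # propagate cue while this stage or a deeper one is gated
      bc <- block_fwd_cache(xc, bp, keep = keep_cache)
      xc <- bc$y
      if (keep_cache) cue_caches[[l]] <- bc
    }
    if (gated[l + 1]) {
      stopifnot(identical(dim(xc), dim(xm)))
      m <- time_average_memory(xc)
      gcl <- gain_fwd(m, net$params$gains[[l + 1]], spec$gain_form)
      pre_gain[[l + 1]] <- xm
      gcaches[[l + 1]] <- gcl
      xm <- apply_gain_map(xm, gcl$g)
    }
    if (capture) stages[[l + 1]] <- xm
  }
  flat <- as.vector(xm)
  z1 <- as.vector(net$params$fc1$W %*% flat) + net$params$fc1$b
  mask1 <- z1 > 0
  h <- ifelse(mask1, z1, 0)
  dropmask <- NULL
  hd <- h
  if (train_mode && spec$dropout_p > 0) {
    keep_p <- 1 - spec$dropout_p
    dropmask <- stats::rbinom(length(h), 1, keep_p) / keep_p
    hd <- h * dropmask
  }
  z2 <- as.vector(net$params$fc2$W %*% hd) + net$params$fc2$b
  probs <- softmax(z2)
  out <- list(probs = probs)
  if (capture) {
    names(stages) <- c("cochleagram", paste0("block", seq_len(L)))
    out$stages <- stages
  }
  if (keep_cache) {
    out$cache <- list(
      mix_caches = mix_caches, cue_caches = cue_caches,
      gcaches = gcaches, pre_gain = pre_gain, gated = gated,
      top_gated = top_gated, flat = flat, dim_final = dim(xm),
      mask1 = mask1, dropmask = dropmask, hd = hd, probs = probs,
      baseline = baseline, L = L
    )
  }
  out
}

#' Cue-gated forward pass of a feature-gain network
#'
#' Propagates the cue (ungated) through the shared convolutional blocks; at
#' the cochleagram stage and after every block, the cue's time-averaged
#' memory is converted into a sigmoidal gain map that multiplies the
#' mixture activation at every timepoint. The final mixture activation is
#' flattened and classified (fully-connected, ReLU, dropout during
#' training, softmax).
#'
#' @param cue,mix `cochleagram`s (or activation arrays) of identical shape.
#' @param net `gain_network` with `variant = "feature-gain"`.
#' @param train_mode apply dropout (TRUE) or run deterministically (FALSE).
#' @return class probability vector (nonnegative, sums to 1).
#' @export
attended_forward <- function(cue, mix, net, train_mode = FALSE) {
  if (net$spec$variant != "feature-gain") {
    stop_config("attended_forward requires a feature-gain network; got ",
                net$spec$variant)
  }
  forward_full(net, cue, mix, train_mode = train_mode)$probs
}

#' Forward pass of the control variants
#'
#' `baseline`: cue and mixture cochleagrams are concatenated on the channel
#' axis and run through a plain (gain-free) network with 4 input channels.
#' `early-only`: a single gain application at the cochleagram stage.
#' `late-only`: a single gain application after the final convolutional
#' block. Everything else matches [attended_forward()].
#'
#' @inheritParams attended_forward
#' @param net `gain_network` with variant `baseline`, `early-only`, or
#'   `late-only`.
#' @return class probability vector.
#' @export
variant_forward <- function(cue, mix, net, train_mode = FALSE) {
  if (!net$spec$variant %in% c("baseline", "early-only", "late-only")) {
    stop_config("variant_forward requires a control variant; got ",
                net$spec$variant)
  }
  forward_full(net, cue, mix, train_mode = train_mode)$probs
}

#' Forward pass with per-stage activation capture
#'
#' Returns the post-gain mixture activation at every stage (the cochleagram
#' stage and each block output), as used by the locus-of-selection analysis.
#'
#' @inheritParams attended_forward
#' @param net `gain_network` (any variant).
#' @return list with `stages` (named list of activation arrays) and `probs`.
#' @export
forward_capture <- function(net, cue, mix) {
  out <- forward_full(net, cue, mix, capture = TRUE)
  list(stages = out$stages, probs = out$probs)
}

# Backward pass: gradients of -log probs[label] w.r.t. all parameters.
# Returns a tree congruent with net$params.
net_backward <- function(net, fwd, label) {
  spec <- net$spec
  cache <- fwd$cache
  L <- cache$L
  params <- net$params
  dz2 <- cache$probs
  dz2[label] <- dz2[label] - 1
  gfc2 <- list(W = dz2 %o% cache$hd, b = dz2)
  dh <- as.vector(crossprod(params$fc2$W, dz2))
  if (!is.null(cache$dropmask)) dh <- dh * cache$dropmask
  dz1 <- dh * cache$mask1
  gfc1 <- list(W = dz1 %o% cache$flat, b = dz1)
  dxm <- array(as.vector(crossprod(params$fc1$W, dz1)), cache$dim_final)
  gblocks <- vector("list", L)
  ggains <- rep(list(c(0, 0, 0)), L + 1)
  dm_inj <- vector("list", L + 1)
  for (l in L:0) {
    s <- l + 1L
    if (cache$gated[s]) {
      gc <- cache$gcaches[[s]]
      pre <- cache$pre_gain[[s]]
      dpre <- apply_gain_map(dxm, gc$g)
      dg <- time_average_memory(dxm * pre) * dim(pre)[3] # sum over time
      gb <- gain_bwd(gc, dg)
      ggains[[s]] <- gb$dtheta
      dm_inj[[s]] <- gb$dm
      dxm <- dpre
    }
    if (l > 0) {
      res <- block_bwd(cache$mix_caches[[l]], dxm)
      gblocks[[l]] <- list(W = res$dW, dgamma = res$dgamma, dbeta = res$dbeta)
      dxm <- res$dx
    }
  }
  # cue path: memory gradients flow into the cue activations and through
  # the shared block weights
  if (!cache$baseline && cache$top_gated >= 0) {
    top <- cache$top_gated
    dxc <- NULL
    for (l in top:0) {
      s <- l + 1L
      if (!is.null(dm_inj[[s]])) {
        cc <- if (l == 0) NULL else cache$cue_caches[[l]]
        Tl <- if (l == 0) spec$input_dim[3] else dim(cc$y)[3]
        inj_dim <- if (l == 0) spec$input_dim else dim(cc$y)
        inj <- array(rep(as.vector(dm_inj[[s]]) / Tl, Tl), inj_dim)
        dxc <- if (is.null(dxc)) inj else dxc + inj
      }
      if (l > 0 && !is.null(dxc)) {
        res <- block_bwd(cache$cue_caches[[l]], dxc)
        gblocks[[l]]$W <- gblocks[[l]]$W + res$dW
        gblocks[[l]]$dgamma <- gblocks[[l]]$dgamma + res$dgamma
        gblocks[[l]]$dbeta <- gblocks[[l]]$dbeta + res$dbeta
        dxc <- res$dx
      }
    }
  }
  list(
    blocks = lapply(seq_len(L), function(l) {
      list(W = gblocks[[l]]$W,
           gamma = array(gblocks[[l]]$dgamma, dim(params$blocks[[l]]$gamma)),
           beta = array(gblocks[[l]]$dbeta, dim(params$blocks[[l]]$beta)))
    }),
    fc1 = gfc1, fc2 = gfc2, gains = ggains
  )
}
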