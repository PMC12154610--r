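# Core tensor operations of the gain-modulated network.
# Activations are 3-d arrays [channels C, frequencies F, time T].
# Each op has a matching *_bwd used by the training harness; forward
# functions are exported as the module surface, backward ones are internal.

#' Layer-normalization parameters
#'
#' @param gamma,beta learnable scale/shift; arrays matching the normalized
#'   activation shape (scalars are broadcast).
#' @param epsilon variance floor, must be positive (default 1e-5).
#' @return list of class `layer_norm_params`.
#' @export
layer_norm_params <- function(gamma = 1, beta = 0, epsilon = 1e-5) {
  if (epsilon <= 0) stop_config("epsilon must be positive")
  structure(list(gamma = gamma, beta = beta, epsilon = epsilon),
            class = "layer_norm_params")
}

#' Layer normalization of a single example
#'
#' Standardizes the activation using the mean and (population) variance over
#' all feature dimensions (C, F, T) of the example, then applies the
#' learnable per-feature scale and shift:
#' `(x - mean(x)) / sqrt(var(x) + epsilon) * gamma + beta`.
#'
#' @param x activation array.
#' @param p `layer_norm_params`.
#' @return normalized array, same shape as `x`.
#' @export
layer_normalize <- function(x, p) {
  if (!(length(p$gamma) == 1 || length(p$gamma) == length(x))) {
    stop_config("gamma shape does not match activation shape")
  }
  if (!(length(p$beta) == 1 || length(p$beta) == length(x))) {
    stop_config("beta shape does not match activation shape")
  }
  mu <- mean(x)
  v <- mean((x - mu)^2)
  xhat <- (x - mu) / sqrt(v + p$epsilon)
  xhat * as.vector(p$gamma) + as.vector(p$beta)
}

# layer norm with cache for backprop
ln_fwd <- function(x, gamma, beta, epsilon = 1e-5) {
  mu <- mean(x)
  v <- mean((x - mu)^2)
  inv <- 1 / sqrt(v + epsilon)
  xhat <- (x - mu) * inv
  list(y = xhat * as.vector(gamma) + as.vector(beta), xhat = xhat, inv = inv)
}

ln_bwd <- function(cache, gamma, dy) {
  n <- length(dy)
  dgamma <- dy * cache$xhat
  dbeta <- dy
  dxhat <- dy * as.vector(gamma)
  dx <- cache$inv * (dxhat - mean(dxhat) - cache$xhat * mean(dxhat * cache$xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- convolution: "valid" in time, zero-padded "same" in frequency -------

# Convolution forward/backward dispatch to compiled loops ("valid" along
# time, zero-padded "same" along frequency, stride 1, no bias). The
# backward pass recomputes from the cached block input, so the forward
# cache is just that input.
conv_fwd <- function(x, W, keep = FALSE) {
  d <- dim(x)
  dw <- dim(W)
  if (dw[2] != d[1]) stop_config("input channel count does not match kernels")
  if (d[3] < dw[4]) {
    stop_input("time axis (", d[3], ") shorter than kernel (", dw[4], ")")
  }
  y <- conv_vs_fwd_cpp(x, as.integer(d), W, as.integer(dw))
  if (keep) list(y = y, x = x, dimx = d) else y
}

conv_bwd <- function(cache, W, dy) {
  conv_vs_bwd_cpp(cache$x, as.integer(cache$dimx), W,
                  as.integer(dim(W)), dy)
}

#' Convolutional block parameters
#'
#' One block = layer normalization, then convolution ("valid" along time,
#' zero-padded "same" along frequency, stride 1, no bias), then ReLU, then
#' anti-aliased Hanning-weighted average pooling.
#'
#' @param kernels array `[C_out, C_in, n_f, n_t]` of filter kernels.
#' @param pool_stride_freq,pool_stride_time pooling strides (>= 1).
#' @param norm `layer_norm_params` for the block input.
#' @return list of class `conv_block_params`.
#' @export
conv_block_params <- function(kernels, pool_stride_freq = 1,
                              pool_stride_time = 1,
                              norm = layer_norm_params()) {
  dw <- dim(kernels)
  if (length(dw) != 4) stop_config("kernels must be a 4-d array")
  if (dw[3] < 1 || dw[4] < 1) stop_config("kernel extents must be >= 1")
  if (pool_stride_freq < 1 || pool_stride_time < 1) {
    stop_config("pool strides must be >= 1")
  }
  structure(list(kernels = kernels, pool_stride_freq = pool_stride_freq,
                 pool_stride_time = pool_stride_time, norm = norm),
            class = "conv_block_params")
}

#' Apply one convolutional block
#'
#' @param x activation array `[C_in, F, T]`.
#' @param p `conv_block_params`.
#' @return activation array `[C_out, F / s_f, (T - n_t + 1) / s_t]` (floor).
#' @export
convolve_block <- function(x, p) {
  y <- layer_normalize(x, p$norm)
  y <- conv_fwd(y, p$kernels)
  y[y < 0] <- 0
  pool_hanning(y, p$pool_stride_freq, p$pool_stride_time)
}

# ---- Hanning-weighted average pooling ------------------------------------

# unit-sum Hanning kernel; extent 1 when stride is 1, else 4 * stride
hanning_kernel <- function(stride) {
  if (stride == 1) return(1)
  L <- 4 * stride
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
  w / sum(w)
}

# pooling operator as a sparse-in-effect dense matrix [n_out x len];
# row j holds the kernel centered at input position (j-1)*stride + 1,
# zero-padded at the boundaries
pool_matrix <- function(len, stride) {
  key <- sprintf("pool_%d_%d", len, stride)
  cache_get(key, function() {
    w <- hanning_kernel(stride)
    L <- length(w)
    n_out <- len %/% stride
    P <- matrix(0, n_out, len)
    off <- -((L - 1) %/% 2)
    for (j in seq_len(n_out)) {
      pos <- (j - 1) * stride + 1 + off + 0:(L - 1)
      ok <- pos >= 1 & pos <= len
      P[j, pos[ok]] <- w[ok]
    }
    P
  })
}

#' Hanning-weighted average pooling
#'
#' Convolves each channel with a separable unit-sum 2-d Hanning kernel whose
#' extent is 1 where the stride is 1 and `4 * stride` otherwise, then
#' subsamples by `(s_f, s_t)`. This lowpass-then-subsample scheme reduces
#' the aliasing that plain strided subsampling would introduce.
#'
#' @param x activation array `[C, F, T]`.
#' @param s_f,s_t strides along frequency and time (>= 1).
#' @return pooled array `[C, floor(F/s_f), floor(T/s_t)]`.
#' @export
pool_hanning <- function(x, s_f, s_t) {
  if (s_f < 1 || s_t < 1) stop_config("pool strides must be >= 1")
  d <- dim(x)
  if (s_t > 1) {
    Pt <- pool_matrix(d[3], s_t)
    xm <- matrix(x, d[1] * d[2], d[3]) %*% t(Pt)
    x <- array(xm, c(d[1], d[2], nrow(Pt)))
    d <- dim(x)
  }
  if (s_f > 1) {
    Pf <- pool_matrix(d[2], s_f)
    xp <- aperm(x, c(2, 1, 3))
    ym <- Pf %*% matrix(xp, d[2], d[1] * d[3])
    x <- aperm(array(ym, c(nrow(Pf), d[1], d[3])), c(2, 1, 3))
  }
  x
}

pool_bwd <- function(dy, dimx, s_f, s_t) {
  d_after_t <- c(dimx[1], dimx[2], if (s_t > 1) dimx[3] %/% s_t else dimx[3])
  dy_arr <- dy
  if (s_f > 1) {
    Pf <- pool_matrix(dimx[2], s_f)
    dp <- aperm(dy_arr, c(2, 1, 3))
    dm <- crossprod(Pf, matrix(dp, dim(dy_arr)[2], dim(dy_arr)[1] * dim(dy_arr)[3]))
    dy_arr <- aperm(array(dm, c(dimx[2], dim(dy_arr)[1], dim(dy_arr)[3])),
                    c(2, 1, 3))
  }
  if (s_t > 1) {
    Pt <- pool_matrix(dimx[3], s_t)
    dm <- matrix(dy_arr, dimx[1] * dimx[2], dim(dy_arr)[3]) %*% Pt
    dy_arr <- array(dm, dimx)
  }
  dy_arr
}

# ---- cue memory and gains ------------------------------------------------

#' Time-averaged cue memory
#'
#' Per-(channel, frequency) arithmetic mean over the time axis of an
#' activation; this is the summary of the cue that drives the gains.
#'
#' @param x activation array `[C, F, T]`.
#' @return matrix `[C, F]`.
#' @export
time_average_memory <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3) stop_input("expected a C x F x T array")
  if (d[3] < 1) stop_input("empty time axis")
  matrix(rowMeans(matrix(x, d[1] * d[2], d[3])), d[1], d[2])
}

#' Gain-function parameters
#'
#' @param theta1 bias: the gain's value for features absent from the cue.
#' @param theta2 slope of the sigmoid.
#' @param theta3 threshold (the cue-activation midpoint).
#' @return list of class `gain_params`.
#' @export
gain_params <- function(theta1 = 1, theta2 = 1, theta3 = 0) {
  if (!all(is.finite(c(theta1, theta2, theta3)))) {
    stop_config("gain parameters must be finite")
  }
  structure(list(theta1 = theta1, theta2 = theta2, theta3 = theta3),
            class = "gain_params")
}

#' Sigmoidal feature gains from a cue memory
#'
#' Elementwise sigmoid of the time-averaged cue memory. Two
#' parameterizations are available:
#' \describe{
#'   \item{`"bounded"` (default)}{`g = theta1 + (1 - theta1) *
#'     logistic(theta2 (m - theta3))`, with limits `{theta1, 1}`: features
#'     strongly active in the cue get gain near 1 and are passed through,
#'     others are scaled toward `theta1`.}
#'   \item{`"printed"`}{`g = theta1 - (1 - theta1) *
#'     logistic(theta2 (m - theta3))`, with limits `{theta1, 2 theta1 - 1}`.}
#' }
#'
#' @param m memory matrix `[C, F]` (any numeric array works).
#' @param p `gain_params`.
#' @param form parameterization, `"bounded"` or `"printed"`.
#' @return gain map, same shape as `m`.
#' @export
compute_gains <- function(m, p, form = c("bounded", "printed")) {
  form <- match.arg(form)
  s <- stats::plogis(p$theta2 * (m - p$theta3))
  if (form == "bounded") p$theta1 + (1 - p$theta1) * s
  else p$theta1 - (1 - p$theta1) * s
}

# gains + partials for backprop; theta = c(theta1, theta2, theta3)
gain_fwd <- function(m, theta, form = "bounded") {
  sgn <- if (form == "bounded") 1 else -1
  s <- stats::plogis(theta[2] * (m - theta[3]))
  list(
    g = theta[1] + sgn * (1 - theta[1]) * s,
    s = s, sgn = sgn, m = m, theta = theta
  )
}

gain_bwd <- function(cache, dg) {
  th <- cache$theta
  s <- cache$s
  sp <- s * (1 - s)
  d1 <- sum(dg * (1 - cache$sgn * s))
  d2 <- sum(dg * cache$sgn * (1 - th[1]) * sp * (cache$m - th[3]))
  d3 <- sum(dg * cache$sgn * (1 - th[1]) * sp * (-th[2]))
  dm <- dg * cache$sgn * (1 - th[1]) * sp * th[2]
  list(dtheta = c(d1, d2, d3), dm = dm)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}
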