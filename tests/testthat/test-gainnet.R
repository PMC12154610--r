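# Network operations: layer norm, convolution, pooling, cue memory,
# sigmoidal gains, and the gated forward passes.

test_that("layer normalization matches its moment contract", {
  p <- layer_norm_params()
  # constant input -> all zeros
  expect_equal(layer_normalize(array(3.2, c(2, 4, 5)), p),
               array(0, c(2, 4, 5)))
  # standardized input passes through (up to the epsilon shrinkage)
  set.seed(1)
  x <- array(rnorm(2 * 4 * 50), c(2, 4, 50))
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  expect_equal(layer_normalize(x, p), x, tolerance = 1e-4)
  # oracle: direct moment computation on the output
  set.seed(2)
  x <- array(rnorm(3 * 5 * 40, sd = 4, mean = 2), c(3, 5, 40))
  y <- layer_normalize(x, p)
  expect_lt(abs(mean(y)), 1e-6)
  expect_equal(mean((y - mean(y))^2), 1, tolerance = 1e-4)
  # gamma/beta are applied elementwise
  g <- array(runif(length(x)), dim(x))
  b <- array(runif(length(x)), dim(x))
  y2 <- layer_normalize(x, layer_norm_params(g, b))
  expect_equal((y2 - b) / g, y, tolerance = 1e-12)
})

test_that("layer normalization rejects mismatched parameter shapes", {
  x <- array(1:24, c(2, 3, 4))
  expect_error(layer_normalize(x, layer_norm_params(gamma = rep(1, 5))),
               class = "gainlisten_config_error")
  expect_error(layer_norm_params(epsilon = 0),
               class = "gainlisten_config_error")
})

test_that("convolution matches a brute-force oracle and its geometry", {
  set.seed(3)
  x <- rand_act(2, 6, 20, seed = 3)
  W <- array(rnorm(4 * 2 * 3 * 5), c(4, 2, 3, 5))
  y <- gainlisten:::conv_fwd(x, W)
  expect_equal(dim(y), c(4, 6, 16)) # T - n_t + 1, F unchanged
  expect_equal(y, oracle_conv(x, W), tolerance = 1e-5)
  # wider instance, even-ish kernel sizes
  x2 <- rand_act(3, 9, 15, seed = 4)
  W2 <- array(rnorm(2 * 3 * 5 * 7), c(2, 3, 5, 7))
  expect_equal(gainlisten:::conv_fwd(x2, W2), oracle_conv(x2, W2),
               tolerance = 1e-5)
})

test_that("a convolutional block reduces time as T - n_t + 1 before pooling", {
  x <- rand_act(2, 8, 100, seed = 5, nonneg = TRUE)
  W <- array(rnorm(3 * 2 * 3 * 5), c(3, 2, 3, 5))
  bp <- conv_block_params(W) # pooling strides 1: pre-pool length visible
  y <- convolve_block(x, bp)
  expect_equal(dim(y), c(3, 8, 96))
})

test_that("an identity block passes standardized nonnegative input through", {
  set.seed(6)
  x <- array(abs(rnorm(1 * 5 * 30)), c(1, 5, 30))
  x <- x / sqrt(mean((x - mean(x))^2)) # unit variance, stays nonnegative
  shift <- array(mean(x), dim(x))
  W <- array(1, c(1, 1, 1, 1))
  bp <- conv_block_params(W, norm = layer_norm_params(beta = shift))
  # LN standardizes then beta restores the mean; 1x1 identity kernel and
  # ReLU leave the nonnegative activations unchanged
  expect_equal(convolve_block(x, bp), x, tolerance = 1e-4)
})

test_that("block input shorter than the time kernel is an error", {
  x <- rand_act(2, 4, 3, seed = 7)
  W <- array(rnorm(2 * 2 * 3 * 5), c(2, 2, 3, 5))
  expect_error(convolve_block(x, conv_block_params(W)),
               class = "gainlisten_input_error")
})

test_that("Hanning pooling matches its kernel rule and oracle", {
  # stride 1 -> identity
  x <- rand_act(2, 6, 20, seed = 8)
  expect_identical(pool_hanning(x, 1, 1), x)
  # stride-dependent kernel extent: 4s for s > 1
  expect_equal(length(gainlisten:::hanning_kernel(4)), 16)
  expect_equal(length(gainlisten:::hanning_kernel(2)), 8)
  expect_equal(gainlisten:::hanning_kernel(1), 1)
  expect_equal(sum(gainlisten:::hanning_kernel(3)), 1)
  # constant input -> constant output at interior points (unit-sum kernel)
  xc <- array(2.5, c(1, 12, 40))
  y <- pool_hanning(xc, 2, 4)
  expect_equal(dim(y), c(1, 6, 10))
  expect_equal(y[1, 3:4, 4:7], matrix(2.5, 2, 4), tolerance = 1e-12)
  # brute-force oracle on a random instance
  xr <- rand_act(2, 8, 24, seed = 9)
  expect_equal(pool_hanning(xr, 2, 4), oracle_pool(xr, 2, 4),
               tolerance = 1e-10)
  expect_equal(pool_hanning(xr, 1, 2), oracle_pool(xr, 1, 2),
               tolerance = 1e-10)
})

test_that("time-averaged memory is the per-feature mean over time", {
  # time-constant input: memory equals any slice
  x <- array(rep(matrix(1:6, 2, 3), 10), c(2, 3, 10))
  expect_equal(time_average_memory(x), matrix(1:6, 2, 3))
  # single timestep
  x1 <- array(rnorm(6), c(2, 3, 1))
  expect_equal(time_average_memory(x1), x1[, , 1])
  # brute-force oracle
  set.seed(10)
  xr <- rand_act(3, 4, 17, seed = 10)
  oracle <- apply(xr, c(1, 2), mean)
  expect_equal(time_average_memory(xr), oracle, tolerance = 1e-7)
  expect_error(time_average_memory(matrix(1, 2, 2)),
               class = "gainlisten_input_error")
})

test_that("gain curves match their limits and special cases", {
  m <- matrix(seq(-3, 3, length.out = 12), 3, 4)
  # attention off: theta1 = 1 gives unit gains everywhere
  expect_equal(compute_gains(m, gain_params(1, 2, 0.5)),
               matrix(1, 3, 4))
  # zero slope: constant (1 + theta1) / 2
  expect_equal(compute_gains(m, gain_params(0.3, 0, 1)),
               matrix((1 + 0.3) / 2, 3, 4))
  # saturation: +/- 50 logistic units from threshold
  p <- gain_params(0.2, 4, 1)
  expect_equal(compute_gains(1 + 50 / 4, p), 1, tolerance = 1e-8)
  expect_equal(compute_gains(1 - 50 / 4, p), 0.2, tolerance = 1e-8)
  # monotone increasing in m for positive slope
  g <- compute_gains(seq(-5, 5, 0.1), p)
  expect_true(all(diff(g) > 0))
  # printed parameterization has limits {theta1, 2 theta1 - 1}
  expect_equal(compute_gains(1 - 50 / 4, p, form = "printed"), 0.2,
               tolerance = 1e-8)
  expect_equal(compute_gains(1 + 50 / 4, p, form = "printed"),
               2 * 0.2 - 1, tolerance = 1e-8)
})

test_that("unit gains collapse every gated variant to the gain-free pass", {
  spec <- tiny_spec()
  net <- init_network(spec, seed = 20, gain_init = c(1, 3, 0.2))
  cue <- rand_act(2, 6, 24, seed = 21, nonneg = TRUE)
  mix <- rand_act(2, 6, 24, seed = 22, nonneg = TRUE)
  p_fg <- attended_forward(cue, mix, net)
  net_eo <- net; net_eo$spec$variant <- "early-only"
  net_lo <- net; net_lo$spec$variant <- "late-only"
  expect_equal(variant_forward(cue, mix, net_eo), p_fg, tolerance = 1e-12)
  expect_equal(variant_forward(cue, mix, net_lo), p_fg, tolerance = 1e-12)
  # and the pass is cue-independent when gains are all 1
  cue2 <- rand_act(2, 6, 24, seed = 23, nonneg = TRUE)
  expect_equal(attended_forward(cue2, mix, net), p_fg, tolerance = 1e-12)
})

test_that("a silent cue yields constant per-stage gains", {
  spec <- tiny_spec()
  net <- init_network(spec, seed = 24, gain_init = c(0.4, 2, 0.1))
  mix <- rand_act(2, 6, 24, seed = 25, nonneg = TRUE)
  cue0 <- array(0, c(2, 6, 24))
  cap <- forward_capture(net, cue0, mix)
  # stage-0 memory is exactly 0, so the stage-0 gain is the sigma(0) constant
  g0 <- compute_gains(0, gain_params(0.4, 2, 0.1))
  expect_equal(cap$stages[["cochleagram"]], mix * g0, tolerance = 1e-12)
  expect_equal(sum(cap$probs), 1, tolerance = 1e-6)
})

test_that("softmax output is a probability vector with lowest-index ties", {
  spec <- tiny_spec()
  net <- init_network(spec, seed = 26)
  cue <- rand_act(2, 6, 24, seed = 27, nonneg = TRUE)
  mix <- rand_act(2, 6, 24, seed = 28, nonneg = TRUE)
  p <- attended_forward(cue, mix, net)
  expect_true(all(p > 0))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(which.max(p) %in% seq_len(spec$n_classes))
  expect_identical(which.max(c(0.3, 0.3, 0.2)), 1L)
})

test_that("gains broadcast over time: time order commutes with gating", {
  spec <- tiny_spec()
  net <- init_network(spec, seed = 29, gain_init = c(0.3, 8, 0.2))
  cue <- rand_act(2, 6, 24, seed = 30, nonneg = TRUE)
  mix <- rand_act(2, 6, 24, seed = 31, nonneg = TRUE)
  perm <- sample(24)
  cap1 <- forward_capture(net, cue, mix)$stages[["cochleagram"]]
  cap2 <- forward_capture(net, cue, mix[, , perm])$stages[["cochleagram"]]
  expect_equal(cap2, cap1[, , perm], tolerance = 1e-12)
})

test_that("evaluation-mode passes are bit-identical across runs", {
  spec <- tiny_spec(dropout_p = 0.5) # dropout present but inactive at eval
  net <- init_network(spec, seed = 32, gain_init = c(0.5, 4, 0.3))
  cue <- rand_act(2, 6, 24, seed = 33, nonneg = TRUE)
  mix <- rand_act(2, 6, 24, seed = 34, nonneg = TRUE)
  set.seed(1); p1 <- attended_forward(cue, mix, net)
  set.seed(999); p2 <- attended_forward(cue, mix, net)
  expect_identical(p1, p2)
})

test_that("variant and architecture mismatches are configuration errors", {
  expect_error(
    network_spec(c(2, 6, 24), list(list(c_out = 2L, n_f = 3L, n_t = 3L)),
                 fc_width = 4L, n_classes = 4L, variant = "baseline"),
    class = "gainlisten_config_error"
  )
  expect_error(
    network_spec(c(4, 6, 24), list(list(c_out = 2L, n_f = 3L, n_t = 3L)),
                 fc_width = 4L, n_classes = 4L, variant = "feature-gain"),
    class = "gainlisten_config_error"
  )
  net <- init_network(tiny_spec(), seed = 1)
  cue <- rand_act(2, 6, 24, seed = 2)
  mix <- rand_act(2, 6, 24, seed = 3)
  expect_error(variant_forward(cue, mix, net),
               class = "gainlisten_config_error")
  netb <- init_network(tiny_spec(input_c = 4L, variant = "baseline"), seed = 1)
  expect_error(attended_forward(cue, mix, netb),
               class = "gainlisten_config_error")
  # cue/mixture shape mismatch
  expect_error(attended_forward(rand_act(2, 6, 20, seed = 4), mix, net),
               class = "gainlisten_input_error")
})

test_that("late-only gains leave pre-final activations at the gain-free pass", {
  spec <- tiny_spec()
  net <- init_network(spec, seed = 35, gain_init = c(0.2, 6, 0.3))
  net$spec$variant <- "late-only"
  net_free <- net
  for (s in seq_along(net_free$params$gains)) {
    net_free$params$gains[[s]][1] <- 1 # theta1 = 1: gains off
  }
  cue <- rand_act(2, 6, 24, seed = 36, nonneg = TRUE)
  mix <- rand_act(2, 6, 24, seed = 37, nonneg = TRUE)
  cap <- forward_capture(net, cue, mix)$stages
  cap_free <- forward_capture(net_free, cue, mix)$stages
  L <- length(cap)
  for (s in seq_len(L - 1)) expect_equal(cap[[s]], cap_free[[s]])
  expect_false(isTRUE(all.equal(cap[[L]], cap_free[[L]])))
})

test_that("baseline variant is a deterministic feedforward pass", {
  netb <- init_network(tiny_spec(input_c = 4L, variant = "baseline"), seed = 38)
  mix <- rand_act(2, 6, 24, seed = 39, nonneg = TRUE)
  silence <- array(0, c(2, 6, 24))
  p1 <- variant_forward(silence, mix, netb)
  p2 <- variant_forward(silence, mix, netb)
  expect_identical(p1, p2)
  expect_equal(sum(p1), 1, tolerance = 1e-6)
})
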