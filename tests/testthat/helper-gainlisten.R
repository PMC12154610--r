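# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive (nested loops, direct formulas) and share
# no code with the implementation they check.

# small random activation array
rand_act <- function(C, F_, T_, seed = 1, nonneg = FALSE) {
  set.seed(seed)
  x <- array(rnorm(C * F_ * T_), c(C, F_, T_))
  if (nonneg) x <- abs(x)
  x
}

# a small feature-gain network over a C x F x T input
tiny_spec <- function(input_c = 2L, F_ = 6L, T_ = 24L, n_classes = 4L,
                      variant = "feature-gain", dropout_p = 0) {
  network_spec(
    input_dim = c(input_c, F_, T_),
    blocks = list(
      list(c_out = 3L, n_f = 3L, n_t = 5L, pool_f = 2L, pool_t = 2L),
      list(c_out = 4L, n_f = 3L, n_t = 3L, pool_f = 1L, pool_t = 2L)
    ),
    fc_width = 6L, n_classes = n_classes, dropout_p = dropout_p,
    variant = variant
  )
}

# --- independent oracles ---------------------------------------------------

# direct-summation convolution: valid in time, zero-padded same in
# frequency, stride 1, no bias
oracle_conv <- function(x, W) {
  d <- dim(x); dw <- dim(W)
  Cin <- d[1]; F_ <- d[2]; T_ <- d[3]
  Cout <- dw[1]; nf <- dw[3]; nt <- dw[4]
  pad <- (nf - 1) %/% 2
  Tout <- T_ - nt + 1
  y <- array(0, c(Cout, F_, Tout))
  for (co in seq_len(Cout)) {
    for (f in seq_len(F_)) {
      for (t in seq_len(Tout)) {
        acc <- 0
        for (ci in seq_len(Cin)) {
          for (df in seq_len(nf)) {
            fi <- f + df - 1 - pad
            if (fi < 1 || fi > F_) next
            for (dt in seq_len(nt)) {
              acc <- acc + W[co, ci, df, dt] * x[ci, fi, t + dt - 1]
            }
          }
        }
        y[co, f, t] <- acc
      }
    }
  }
  y
}

# direct weighted-average pooling with a unit-sum separable Hanning kernel
oracle_pool <- function(x, s_f, s_t) {
  hk <- function(s) {
    if (s == 1) return(1)
    L <- 4 * s
    w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
    w / sum(w)
  }
  d <- dim(x)
  wf <- hk(s_f); wt <- hk(s_t)
  k2 <- outer(wf, wt)
  Fo <- d[2] %/% s_f; To <- d[3] %/% s_t
  offf <- -((length(wf) - 1) %/% 2)
  offt <- -((length(wt) - 1) %/% 2)
  y <- array(0, c(d[1], Fo, To))
  for (c in seq_len(d[1])) {
    for (jf in seq_len(Fo)) {
      for (jt in seq_len(To)) {
        cf <- (jf - 1) * s_f + 1
        ct <- (jt - 1) * s_t + 1
        acc <- 0
        for (a in seq_along(wf)) {
          fi <- cf + offf + a - 1
          if (fi < 1 || fi > d[2]) next
          for (b in seq_along(wt)) {
            ti <- ct + offt + b - 1
            if (ti < 1 || ti > d[3]) next
            acc <- acc + k2[a, b] * x[c, fi, ti]
          }
        }
        y[c, jf, jt] <- acc
      }
    }
  }
  y
}

# magnitude spectrum peak frequencies of a mono waveform
peak_freqs <- function(w, min_prominence = 0.1) {
  x <- w$samples[1, ]
  n <- length(x)
  sp <- Mod(fft(x))[seq_len(n %/% 2)]
  sp <- sp / max(sp)
  f <- (seq_len(n %/% 2) - 1) * w$sample_rate / n
  is_peak <- c(FALSE, sp[2:(length(sp) - 1)] > sp[1:(length(sp) - 2)] &
                 sp[2:(length(sp) - 1)] > sp[3:length(sp)], FALSE)
  f[is_peak & sp > min_prominence]
}

# third-octave band energies (dB) of a mono waveform
band_energies_db <- function(w, centers) {
  x <- w$samples[1, ]
  n <- length(x)
  sp <- Mod(fft(x))[seq_len(n %/% 2)]^2
  f <- (seq_len(n %/% 2) - 1) * w$sample_rate / n
  vapply(centers, function(fc) {
    lo <- fc / 2^(1 / 6); hi <- fc * 2^(1 / 6)
    10 * log10(sum(sp[f >= lo & f < hi]))
  }, numeric(1))
}
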