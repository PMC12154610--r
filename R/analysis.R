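# Behavioural scoring, psychometric thresholds, resampling statistics,
# human-model similarity, and the layer-wise locus-of-selection analysis.

#' Score one word-report response
#'
#' A response is correct if it matches any in-vocabulary word of the target
#' transcript, and a confusion if it matches any in-vocabulary word of the
#' distractor transcript; both can be false, and both flags are recorded
#' when both hold. The same rule is applied to human and model reports.
#'
#' @param response reported word (must be in `vocabulary`).
#' @param target_words target transcript.
#' @param distractor_words distractor transcript (may be empty).
#' @param vocabulary the response vocabulary.
#' @return named logical vector `c(correct =, confusion =)`.
#' @export
score_response <- function(response, target_words, distractor_words,
                           vocabulary) {
  if (!response %in% vocabulary) {
    stop_input("out-of-vocabulary response: ", response)
  }
  c(correct = response %in% intersect(target_words, vocabulary),
    confusion = response %in% intersect(distractor_words, vocabulary))
}

#' Speech reception threshold from a performance-by-SNR curve
#'
#' Fits a least-squares second-order polynomial to performance as a
#' function of SNR and solves for the SNR at the criterion level: half the
#' maximum observed performance (`"fraction-of-max"`) or an absolute 50%
#' correct (`"absolute-50"`). When the quadratic crosses the criterion
#' twice, the crossing where performance rises with SNR is taken
#' (psychometric monotonicity); a root outside the tested SNR span is
#' flagged as extrapolated. Optional bootstrap over the rows of
#' `boot_matrix` (participants or architectures) gives the threshold
#' spread.
#'
#' @param snr_levels tested SNRs, dB (>= 3 values).
#' @param performance proportion correct at each SNR, in `[0, 1]`.
#' @param criterion `"fraction-of-max"` or `"absolute-50"`.
#' @param boot_matrix optional matrix (rows = participants/architectures,
#'   columns = SNR levels) to bootstrap over.
#' @param n_boot bootstrap resamples (default 1000).
#' @return list of class `threshold_estimate` with `srt` (dB),
#'   `criterion`, `criterion_level`, `poly_coeffs` (intercept, linear,
#'   quadratic), `extrapolated`, `bootstrap_sd`, `n_boot`.
#' @export
estimate_threshold <- function(snr_levels, performance,
                               criterion = c("fraction-of-max", "absolute-50"),
                               boot_matrix = NULL, n_boot = 1000) {
  criterion <- match.arg(criterion)
  if (length(snr_levels) < 3) stop_input("need at least 3 SNR levels")
  if (length(snr_levels) != length(performance)) {
    stop_input("snr_levels and performance lengths differ")
  }
  if (any(performance < 0 | performance > 1)) {
    stop_input("performance must lie in [0, 1]")
  }
  fit_one <- function(perf) {
    co <- stats::coef(stats::lm(perf ~ snr_levels + I(snr_levels^2)))
    lev <- if (criterion == "fraction-of-max") 0.5 * max(perf) else 0.5
    list(co = co, lev = lev)
  }
  solve_srt <- function(co, lev) {
    c0 <- co[1] - lev; c1 <- co[2]; c2 <- co[3]
    span <- range(snr_levels)
    if (abs(c2) < 1e-12) {
      if (abs(c1) < 1e-12) return(list(srt = NA_real_, extrapolated = TRUE))
      r <- -c0 / c1
      return(list(srt = unname(r), extrapolated = r < span[1] | r > span[2]))
    }
    disc <- c1^2 - 4 * c2 * c0
    if (disc < 0) {
      # no real crossing: report the SNR where the fitted curve is closest
      r <- -c1 / (2 * c2)
      return(list(srt = unname(r), extrapolated = TRUE))
    }
    roots <- (-c1 + c(-1, 1) * sqrt(disc)) / (2 * c2)
    slope <- c1 + 2 * c2 * roots
    rising <- roots[slope > 0]
    cand <- if (length(rising)) rising else roots
    inside <- cand[cand >= span[1] & cand <= span[2]]
    if (length(inside)) {
      return(list(srt = unname(inside[which.min(abs(inside - mean(span)))]),
                  extrapolated = FALSE))
    }
    r <- cand[which.min(pmin(abs(cand - span[1]), abs(cand - span[2])))]
    list(srt = unname(r), extrapolated = TRUE)
  }
  f <- fit_one(performance)
  sol <- solve_srt(f$co, f$lev)
  boot_sd <- NA_real_
  if (!is.null(boot_matrix)) {
    stopifnot(ncol(boot_matrix) == length(snr_levels))
    vals <- vapply(seq_len(n_boot), function(i) {
      rows <- sample(nrow(boot_matrix), replace = TRUE)
      fb <- fit_one(colMeans(boot_matrix[rows, , drop = FALSE]))
      solve_srt(fb$co, fb$lev)$srt
    }, numeric(1))
    boot_sd <- stats::sd(vals, na.rm = TRUE)
  }
  structure(
    list(srt = sol$srt, criterion = criterion, criterion_level = f$lev,
         poly_coeffs = unname(f$co), extrapolated = sol$extrapolated,
         bootstrap_sd = boot_sd,
         n_boot = if (is.null(boot_matrix)) 0L else n_boot),
    class = "threshold_estimate"
  )
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<SRT %.2f dB at criterion %.3f (%s)%s>\n", x$srt,
              x$criterion_level, x$criterion,
              if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}

# interaction statistic of a subjects x cells value matrix, where cells
# enumerate a complete a x b factorial design (column order: a fastest)
interaction_stat <- function(V, a, b) {
  cm <- matrix(colMeans(V), a, b)
  int <- cm - outer(rowMeans(cm), rep(1, b)) -
    outer(rep(1, a), colMeans(cm)) + mean(cm)
  sum(int^2)
}

#' Subject-level permutation test for a threshold interaction
#'
#' The interaction of a complete two-factor design is measured after
#' subtracting each factor's marginal contribution:
#' `interaction_ij = mean threshold_ij - mu_A(i) - mu_B(j) + mu_total`,
#' with the overall statistic the sum of squared interaction terms. The
#' null distribution permutes the factor-cell labels independently within
#' each subject; the p-value uses the add-one convention
#' `p = (1 + #(null >= observed)) / (1 + n_perm)` and is therefore never
#' exactly zero.
#'
#' @param thresholds 3-d array `[subject, factorA, factorB]` with no
#'   missing cells.
#' @param n_perm number of permutations (default 10000).
#' @return list of class `interaction_test` with `observed_statistic`,
#'   `null_samples`, `p_value`, `n_permutations`.
#' @export
interaction_permutation_test <- function(thresholds, n_perm = 10000) {
  d <- dim(thresholds)
  if (is.null(d) || length(d) != 3) {
    stop_input("thresholds must be a subject x factorA x factorB array")
  }
  if (any(!is.finite(thresholds))) {
    stop_input("missing cells are not allowed (no imputation)")
  }
  S <- d[1]; a <- d[2]; b <- d[3]
  V <- matrix(thresholds, S, a * b) # row s = subject s, cells a-fastest
  obs <- interaction_stat(V, a, b)
  nulls <- numeric(n_perm)
  nc <- a * b
  for (p in seq_len(n_perm)) {
    Vp <- V
    for (s in seq_len(S)) Vp[s, ] <- V[s, sample.int(nc)]
    nulls[p] <- interaction_stat(Vp, a, b)
  }
  pval <- (1 + sum(nulls >= obs)) / (1 + n_perm)
  structure(
    list(observed_statistic = obs, null_samples = nulls, p_value = pval,
         n_permutations = n_perm),
    class = "interaction_test"
  )
}

#' @export
print.interaction_test <- function(x, ...) {
  cat(sprintf("<interaction test: statistic %.4g, p = %.4g (%d perms)>\n",
              x$observed_statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' Aggregate human-model similarity
#'
#' Compares aligned per-condition mean performance vectors with
#' root-mean-squared error and the squared Pearson correlation. When
#' per-architecture score distributions are supplied for two model
#' families, they are compared by a two-tailed sign test on the paired
#' differences, with the difference of means as the effect size.
#'
#' @param human_means,model_means aligned per-condition values (>= 3).
#' @param paired_scores optional list with elements `a` and `b`: paired
#'   per-architecture similarity scores to contrast.
#' @return list with `rmse`, `pearson`, `r_squared`, and optionally
#'   `sign_test` (`p_value`, `mean_difference`, `n`).
#' @export
human_model_similarity <- function(human_means, model_means,
                                   paired_scores = NULL) {
  if (length(human_means) != length(model_means)) {
    stop_input("condition vectors differ in length")
  }
  if (length(human_means) < 3) stop_input("need at least 3 conditions")
  rmse <- sqrt(mean((human_means - model_means)^2))
  r <- if (stats::sd(human_means) == 0 || stats::sd(model_means) == 0) {
    NA_real_ # correlation undefined for a zero-variance vector
  } else {
    stats::cor(human_means, model_means)
  }
  out <- list(rmse = rmse, pearson = r, r_squared = r^2)
  if (!is.null(paired_scores)) {
    da <- paired_scores$a
    db <- paired_scores$b
    if (length(da) != length(db)) stop_input("paired score lengths differ")
    diffs <- da - db
    nz <- diffs[diffs != 0]
    st <- stats::binom.test(sum(nz > 0), length(nz), 0.5,
                            alternative = "two.sided")
    out$sign_test <- list(p_value = st$p.value,
                          mean_difference = mean(diffs), n = length(diffs))
  }
  out
}

#' Layer-wise locus-of-selection profile
#'
#' For each trial, the isolated target, the isolated distractor, and their
#' mixture are passed through the network with the same cue (so the same
#' gains apply to all three), and the Pearson correlation between the
#' flattened mixture activation and each isolated-source activation is
#' computed at every stage, including the (gated) cochleagram. Stages
#' where an activation is constant are excluded for that pair, with the
#' exclusion count reported.
#'
#' @param net `gain_network`.
#' @param trials list of trials, each with `cue`, `target`, `distractor`,
#'   `mixture` cochleagrams (or activation arrays).
#' @param snr nominal SNR of the mixtures, recorded on the result.
#' @return data.frame of class `selection_profile` with one row per stage:
#'   `stage`, `corr_target`, `corr_distractor`, `gap` (target minus
#'   distractor), `n_pairs`, `n_excluded`. Per-trial correlations are
#'   attached as attributes `"target_by_trial"` / `"distractor_by_trial"`.
#' @export
selection_profile <- function(net, trials, snr = 0) {
  L <- length(net$spec$blocks)
  n_stage <- L + 1
  ct <- matrix(NA_real_, length(trials), n_stage)
  cd <- matrix(NA_real_, length(trials), n_stage)
  stage_names <- NULL
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    sm <- forward_capture(net, tr$cue, tr$mixture)$stages
    st <- forward_capture(net, tr$cue, tr$target)$stages
    sd_ <- forward_capture(net, tr$cue, tr$distractor)$stages
    if (is.null(stage_names)) stage_names <- names(sm)
    for (s in seq_len(n_stage)) {
      m <- as.vector(sm[[s]])
      if (stats::sd(m) == 0) next
      tv <- as.vector(st[[s]])
      dv <- as.vector(sd_[[s]])
      if (stats::sd(tv) > 0) ct[i, s] <- stats::cor(m, tv)
      if (stats::sd(dv) > 0) cd[i, s] <- stats::cor(m, dv)
    }
  }
  out <- data.frame(
    stage = stage_names,
    corr_target = colMeans(ct, na.rm = TRUE),
    corr_distractor = colMeans(cd, na.rm = TRUE),
    gap = colMeans(ct - cd, na.rm = TRUE),
    n_pairs = colSums(!is.na(ct) & !is.na(cd)),
    n_excluded = colSums(is.na(ct) | is.na(cd)),
    stringsAsFactors = FALSE
  )
  attr(out, "target_by_trial") <- ct
  attr(out, "distractor_by_trial") <- cd
  attr(out, "snr") <- snr
  class(out) <- c("selection_profile", class(out))
  out
}
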