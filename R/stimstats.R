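# Stimulus acoustics and matching statistics: envelope extraction, RMS
# normalisation, cosine-similarity permutation tests over the item
# dimension, the pairwise representational similarity matrix, and a robust
# Bayesian spectrum comparison with a region of practical equivalence.

#' Temporal envelope of a speech waveform at 400 Hz
#'
#' Half-wave rectifies the signal (negative samples to zero), takes the
#' Hilbert magnitude, anti-alias filters and downsamples to `fs_out`.
#'
#' @param audio Mono numeric waveform.
#' @param fs_in Input sampling rate in Hz.
#' @param fs_out Output envelope rate (default 400 Hz).
#' @return Non-negative numeric envelope of length
#'   `round(duration * fs_out)`.
#' @export
extract_envelope <- function(audio, fs_in, fs_out = 400) {
  if (!length(audio)) abort("empty audio")
  rectified <- pmax(audio, 0)
  env <- Mod(analytic_signal(rectified))
  n_out <- round(length(audio) / fs_in * fs_out)
  resample_envelope(env, fs_in, fs_out, n_out)
}

#' Normalise a signal to a target RMS level
#'
#' Scales the signal so its root-mean-square value equals
#' `10^(target_db / 20)` of full scale; idempotent and scale invariant.
#'
#' @param audio Nonzero numeric signal.
#' @param target_db Target RMS in dB full scale (default -16).
#' @return Scaled signal.
#' @export
rms_normalize <- function(audio, target_db = -16) {
  r <- signal_rms(audio)
  if (r == 0) abort("cannot RMS-normalise an all-zero signal")
  audio * 10^(target_db / 20) / r
}

# cosine similarity between two vectors; NA for zero norms
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Per-time-bin cosine similarity between two envelope sets
#'
#' After moving-average smoothing (`smooth_ms`), every time bin is compared
#' across the item dimension: the bin's values over all items of set A form
#' one vector, those of set B another, and their cosine similarity is
#' recorded. The permutation null shuffles each B envelope's time bins
#' independently and keeps the maximum similarity over bins (`n_perm`
#' times); the threshold is the null's 95th percentile. The item-pair representational similarity matrix
#' (RSM) of whole envelopes is computed with an analogous shuffled null.
#'
#' @param env_a,env_b Item x time envelope matrices (equal shapes), or
#'   `envelope_set` objects.
#' @param n_perm Permutations (default 1000).
#' @param smooth_ms Smoothing window in ms (default 50).
#' @param fs Envelope sampling rate in Hz (default 400; taken from
#'   `envelope_set` inputs).
#' @param alpha Significance level of the max-statistic null (default 0.05).
#' @param seed Integer seed.
#' @return A `similarity_result`: list with `profile` tibble (time,
#'   similarity, above_threshold), `threshold`, `rsm` (matrix), `rsm_threshold`,
#'   `rsm_frac_similar`.
#' @export
similarity_tests <- function(env_a, env_b, n_perm = 1000, smooth_ms = 50,
                             fs = 400, alpha = 0.05, seed = 1) {
  if (inherits(env_a, "envelope_set")) { fs <- env_a$fs; env_a <- env_a$env }
  if (inherits(env_b, "envelope_set")) env_b <- env_b$env
  if (!all(dim(env_a) == dim(env_b))) abort("envelope sets must match in shape")
  k <- max(1, round(smooth_ms / 1000 * fs))
  sm <- function(m) t(apply(m, 1, function(x) {
    as.numeric(stats::filter(x, rep(1 / k, k), sides = 2, circular = TRUE))
  }))
  A <- sm(env_a); B <- sm(env_b)
  n_time <- ncol(A)
  profile <- vapply(seq_len(n_time), function(t) cosine_similarity(A[, t], B[, t]),
                    numeric(1))
  set.seed(substream_seed(seed, "similarity"))
  null_max <- vapply(seq_len(n_perm), function(p) {
    # each item's time course shuffled independently
    Bp <- t(apply(B, 1, function(r) r[sample.int(n_time)]))
    max(vapply(seq_len(n_time), function(t) {
      cosine_similarity(A[, t], Bp[, t])
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  thr <- quantile(null_max, 1 - alpha, names = FALSE)
  # RSM over whole envelopes, all items pooled
  all_env <- rbind(env_a, env_b)
  n_items <- nrow(all_env)
  rsm <- matrix(1, n_items, n_items)
  for (i in seq_len(n_items - 1)) {
    for (j in (i + 1):n_items) {
      rsm[i, j] <- rsm[j, i] <- cosine_similarity(all_env[i, ], all_env[j, ])
    }
  }
  null_rsm <- vapply(seq_len(n_perm), function(p) {
    i <- sample.int(n_items, 1); j <- sample.int(n_items, 1)
    cosine_similarity(all_env[i, ], all_env[j, sample.int(ncol(all_env))])
  }, numeric(1))
  rsm_thr <- quantile(null_rsm, 1 - alpha, names = FALSE)
  off <- rsm[upper.tri(rsm)]
  structure(
    list(
      profile = tibble::tibble(
        time = (seq_len(n_time) - 1) / fs,
        similarity = profile,
        above_threshold = !is.na(profile) & profile > thr
      ),
      threshold = thr,
      rsm = rsm, rsm_threshold = rsm_thr,
      rsm_frac_similar = mean(off > rsm_thr, na.rm = TRUE)
    ),
    class = "similarity_result"
  )
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(
    "<similarity_result: %.1f%% of bins above threshold %.3f; RSM %.1f%% similar>\n",
    100 * mean(x$profile$above_threshold, na.rm = TRUE), x$threshold,
    100 * x$rsm_frac_similar
  ))
  invisible(x)
}

#' Similarity profile plot
#'
#' @param object A `similarity_result`.
#' @param ... Unused.
#' @export
autoplot.similarity_result <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(.data$time, .data$similarity)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "time (s)", y = "cosine similarity") +
    ggplot2::theme_minimal()
}

#' Robust Bayesian spectrum comparison with a ROPE decision
#'
#' Per frequency bin above `min_freq`: DFT intensities of each item's
#' envelope form two groups. Both group means get a gamma prior whose mean
#' equals the pooled sample mean and whose SD is five times the pooled SD;
#' the likelihood is a t distribution with fixed normality parameter
#' `nu = 30` and a half-Cauchy-ish (folded) prior on each group SD. The
#' posterior of the standardised mean difference is sampled by
#' Metropolis-within-Gibbs; the decision is "difference" if 0 lies outside
#' the 95% highest density interval, "equivalence" if the HDI lies inside
#' `rope`, otherwise "undecided".
#'
#' @param env_a,env_b Item x time envelope matrices or `envelope_set`s.
#' @param rope Region of practical equivalence on the standardised
#'   difference (default c(-0.1, 0.1)).
#' @param nu Fixed t-likelihood normality parameter (default 30).
#' @param n_iter,n_warmup MCMC iterations after / of warm-up (defaults
#'   10000, 2000).
#' @param fs Envelope sampling rate (default 400 Hz).
#' @param min_freq Lowest analysed frequency in Hz (default 1).
#' @param max_bins Cap on the number of analysed bins, taken from the low
#'   end (default 40); keeps run time bounded.
#' @param seed Integer seed.
#' @return A `spectrum_rope` tibble: freq, mean_a, mean_b, hdi_low,
#'   hdi_high, decision, rhat.
#' @export
spectrum_rope <- function(env_a, env_b, rope = c(-0.1, 0.1), nu = 30,
                          n_iter = 10000, n_warmup = 2000, fs = 400,
                          min_freq = 1, max_bins = 40, seed = 1) {
  if (inherits(env_a, "envelope_set")) { fs <- env_a$fs; env_a <- env_a$env }
  if (inherits(env_b, "envelope_set")) env_b <- env_b$env
  if (nrow(env_a) < 5 || nrow(env_b) < 5) abort("need >= 5 items per condition")
  n_time <- ncol(env_a)
  freqs <- (seq_len(n_time) - 1) * fs / n_time
  keep <- which(freqs > min_freq & freqs <= fs / 2)
  keep <- head(keep, max_bins)
  spec <- function(m) t(apply(m, 1, function(x) Mod(fft(x)) / length(x)))
  Ia <- spec(env_a)[, keep, drop = FALSE]
  Ib <- spec(env_b)[, keep, drop = FALSE]
  rows <- lapply(seq_along(keep), function(k) {
    fit <- best_two_group(Ia[, k], Ib[, k], nu = nu, n_iter = n_iter,
                          n_warmup = n_warmup,
                          seed = substream_seed(seed, k))
    hdi <- hdi_interval(fit$delta_std, 0.95)
    decision <- if (hdi[1] > 0 || hdi[2] < 0) {
      "difference"
    } else if (hdi[1] >= rope[1] && hdi[2] <= rope[2]) {
      "equivalence"
    } else {
      "undecided"
    }
    tibble::tibble(
      freq = freqs[keep[k]],
      mean_a = mean(Ia[, k]), mean_b = mean(Ib[, k]),
      hdi_low = hdi[1], hdi_high = hdi[2],
      decision = decision, rhat = fit$rhat
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("spectrum_rope", class(out))
  out
}

# BEST-like two-group model: t likelihood with fixed nu, gamma prior on
# each group mean (pooled mean / 5x pooled SD), log-normal prior on SDs.
# Random-walk Metropolis-within-Gibbs over (mu1, mu2, log s1, log s2).
best_two_group <- function(y1, y2, nu = 30, n_iter = 10000, n_warmup = 2000,
                           seed = 1) {
  set.seed(seed)
  pool <- c(y1, y2)
  pm <- mean(pool)
  ps <- max(sd(pool), .Machine$double.eps)
  prior_sd <- 5 * ps
  # gamma prior parameterised by mean pm and sd prior_sd
  sh <- (pm / prior_sd)^2
  ra <- pm / prior_sd^2
  log_prior_mu <- function(mu) {
    if (mu <= 0) return(-Inf)
    dgamma(mu, shape = sh, rate = ra, log = TRUE)
  }
  log_prior_logsd <- function(ls) dnorm(ls, log(ps), 2, log = TRUE)
  loglik <- function(y, mu, s) sum(dt((y - mu) / s, df = nu, log = TRUE) - log(s))
  run_chain <- function(mu1, mu2, ls1, ls2) {
    keep <- matrix(0, n_iter, 3)
    lp1 <- loglik(y1, mu1, exp(ls1)) + log_prior_mu(mu1) + log_prior_logsd(ls1)
    lp2 <- loglik(y2, mu2, exp(ls2)) + log_prior_mu(mu2) + log_prior_logsd(ls2)
    n_obs <- length(y1) + length(y2)
    step_mu <- 2.4 * ps / sqrt(n_obs / 2)
    step_ls <- max(0.05, 2.4 / sqrt(n_obs))
    for (it in seq_len(n_warmup + n_iter)) {
      # group 1
      mu1p <- mu1 + rnorm(1, sd = step_mu)
      lp1p <- loglik(y1, mu1p, exp(ls1)) + log_prior_mu(mu1p) + log_prior_logsd(ls1)
      if (log(runif(1)) < lp1p - lp1) { mu1 <- mu1p; lp1 <- lp1p }
      ls1p <- ls1 + rnorm(1, sd = step_ls)
      lp1p <- loglik(y1, mu1, exp(ls1p)) + log_prior_mu(mu1) + log_prior_logsd(ls1p)
      if (log(runif(1)) < lp1p - lp1) { ls1 <- ls1p; lp1 <- lp1p }
      # group 2
      mu2p <- mu2 + rnorm(1, sd = step_mu)
      lp2p <- loglik(y2, mu2p, exp(ls2)) + log_prior_mu(mu2p) + log_prior_logsd(ls2)
      if (log(runif(1)) < lp2p - lp2) { mu2 <- mu2p; lp2 <- lp2p }
      ls2p <- ls2 + rnorm(1, sd = step_ls)
      lp2p <- loglik(y2, mu2, exp(ls2p)) + log_prior_mu(mu2) + log_prior_logsd(ls2p)
      if (log(runif(1)) < lp2p - lp2) { ls2 <- ls2p; lp2 <- lp2p }
      if (it > n_warmup) {
        keep[it - n_warmup, ] <- c(mu1, mu2, sqrt((exp(2 * ls1) + exp(2 * ls2)) / 2))
      }
    }
    keep
  }
  init_jitter <- function(x) x * (1 + runif(1, -0.05, 0.05)) + 1e-12
  c1 <- run_chain(init_jitter(mean(y1)), init_jitter(mean(y2)),
                  log(max(sd(y1), ps / 10)), log(max(sd(y2), ps / 10)))
  c2 <- run_chain(init_jitter(mean(y1)), init_jitter(mean(y2)),
                  log(max(sd(y1), ps / 10)) + 0.2, log(max(sd(y2), ps / 10)) - 0.2)
  delta1 <- (c1[, 1] - c1[, 2]) / c1[, 3]
  delta2 <- (c2[, 1] - c2[, 2]) / c2[, 3]
  list(delta_std = c(delta1, delta2), rhat = split_rhat(delta1, delta2),
       prior_mean = pm)
}

# split-chain potential scale reduction on two chains
split_rhat <- function(a, b) {
  half <- function(x) {
    n <- floor(length(x) / 2)
    list(x[seq_len(n)], x[n + seq_len(n)])
  }
  chains <- c(half(a), half(b))
  n <- length(chains[[1]])
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# highest density interval of a sample
hdi_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1, floor(prob * n))
  widths <- x[(k + 1):n] - x[seq_len(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}
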