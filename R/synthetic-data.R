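# Synthetic stimulus envelopes and multichannel trial data with planted,
# parameterised effects: every downstream analysis stage has a known ground
# truth to recover. The generator emulates the statistical structure the
# analyses assume (low-frequency phase locking to onset, alpha-band induced
# power change, theta-phase/gamma-amplitude coupling, inter-channel phase
# structure, kernel-convolved envelope responses) on top of broadband noise;
# it makes no attempt to emulate recording artifacts.

#' Planted ground truth for the synthetic trial generator
#'
#' All effect fields are optional (`NULL` disables the component).
#'
#' @param phase_lock `list(freq, strength, channels)` — stimulus-locked
#'   oscillation at `freq` Hz whose inter-trial phase concentration equals
#'   `strength` in \[0,1\] (1 = identical phase every trial).
#' @param alpha `list(freq, db, channels)` — oscillation whose post-onset
#'   amplitude is scaled so induced power changes by `db` decibels relative
#'   to baseline.
#' @param pac `list(phase_freq, amp_freq, depth, channels, scale)` —
#'   amplitude at `amp_freq` modulated by `1 + depth * cos(phase)` of a
#'   `phase_freq` oscillation; `depth` in \[0,1\].
#' @param kernel Channel x band x lag encoding kernel (causal lags, in
#'   samples at the trial sampling rate), convolved with 16-band envelope
#'   features when `envelopes` are supplied to [gen_trials()].
#' @param conn `list(freq, groups, lags)` — channel groups sharing one
#'   random per-trial phase at `freq` Hz (high within-group phase-lag
#'   consistency), with fixed per-channel lags in radians.
#' @param noise_sd SD of additive Gaussian white noise (a.u.).
#' @param pink Add a 1/f noise component of the same SD.
#' @param seed Integer; fully determines the generated tensors.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(phase_lock = NULL, alpha = NULL, pac = NULL,
                         kernel = NULL, conn = NULL, noise_sd = 1,
                         pink = FALSE, seed = 1) {
  chk01 <- function(v, what) {
    if (!is.null(v) && (v < 0 || v > 1)) abort(paste(what, "must be in [0,1]"))
  }
  chk01(phase_lock$strength, "phase_lock$strength")
  chk01(pac$depth, "pac$depth")
  if (!is.null(kernel) && length(dim(kernel)) != 3) {
    abort("kernel must be a channel x band x lag array")
  }
  structure(
    list(phase_lock = phase_lock, alpha = alpha, pac = pac, kernel = kernel,
         conn = conn, noise_sd = noise_sd, pink = pink, seed = seed),
    class = "ground_truth"
  )
}

#' Generate multichannel trials with planted effects
#'
#' @param truth A [ground_truth()] description.
#' @param n_trials Number of trials (>= 2).
#' @param n_channels Number of channels.
#' @param fs Sampling rate in Hz (default 256); must be at least 4x the
#'   highest planted frequency.
#' @param epoch_window Epoch in seconds relative to onset
#'   (default c(-1, 2)); needs >= 0.8 s baseline.
#' @param envelopes Optional `envelope_set` (see [gen_envelopes()]) or band
#'   x time feature matrix used with `truth$kernel`; one item is drawn per
#'   trial.
#' @param condition Optional per-trial labels.
#' @return A `trial_tensor`.
#' @export
gen_trials <- function(truth, n_trials, n_channels, fs = 256,
                       epoch_window = c(-1, 2), envelopes = NULL,
                       condition = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_trials < 2) abort("need at least 2 trials")
  top_freq <- max(c(truth$phase_lock$freq, truth$alpha$freq,
                    truth$pac$amp_freq, truth$conn$freq, 1))
  if (fs < 4 * top_freq) abort("fs must be >= 4x the highest planted frequency")
  set.seed(substream_seed(truth$seed, "trials"))
  n_time <- round((epoch_window[2] - epoch_window[1]) * fs)
  times <- epoch_window[1] + (seq_len(n_time) - 1) / fs
  post <- times >= 0
  data <- array(rnorm(n_trials * n_channels * n_time, sd = truth$noise_sd),
                dim = c(n_trials, n_channels, n_time))
  if (truth$pink) {
    for (tr in seq_len(n_trials)) {
      for (ch in seq_len(n_channels)) {
        data[tr, ch, ] <- data[tr, ch, ] + pink_noise(n_time, truth$noise_sd)
      }
    }
  }

  if (!is.null(truth$phase_lock)) {
    pl <- truth$phase_lock
    chans <- pl$channels %||% seq_len(n_channels)
    # phase mixture: locked with probability `strength`, uniform otherwise,
    # so the expected inter-trial resultant equals `strength` exactly
    locked <- runif(n_trials) < pl$strength
    phases <- ifelse(locked, 0, runif(n_trials, -pi, pi))
    for (tr in seq_len(n_trials)) {
      osc <- cos(2 * pi * pl$freq * times + phases[tr]) * post
      for (ch in chans) data[tr, ch, ] <- data[tr, ch, ] + osc
    }
  }

  if (!is.null(truth$alpha)) {
    al <- truth$alpha
    chans <- al$channels %||% seq_len(n_channels)
    a0 <- al$baseline_amp %||% 1
    a1 <- a0 * 10^(al$db / 20)
    amp <- ifelse(post, a1, a0)
    for (tr in seq_len(n_trials)) {
      ph <- runif(1, -pi, pi)
      osc <- amp * cos(2 * pi * al$freq * times + ph)
      for (ch in chans) data[tr, ch, ] <- data[tr, ch, ] + osc
    }
  }

  if (!is.null(truth$pac)) {
    pc <- truth$pac
    chans <- pc$channels %||% seq_len(n_channels)
    sc <- pc$scale %||% 1
    for (tr in seq_len(n_trials)) {
      ph0 <- runif(1, -pi, pi)
      slow_phase <- 2 * pi * pc$phase_freq * times + ph0
      carrier <- cos(2 * pi * pc$amp_freq * times + runif(1, -pi, pi))
      comp <- sc * (1 + pc$depth * cos(slow_phase)) * carrier * post
      slow <- cos(slow_phase) * post
      for (ch in chans) data[tr, ch, ] <- data[tr, ch, ] + comp + slow
    }
  }

  if (!is.null(truth$conn)) {
    cn <- truth$conn
    for (tr in seq_len(n_trials)) {
      for (g in seq_along(cn$groups)) {
        theta <- runif(1, -pi, pi)
        for (ch in cn$groups[[g]]) {
          lag <- (cn$lags %||% rep(0, n_channels))[ch]
          data[tr, ch, ] <- data[tr, ch, ] +
            cos(2 * pi * cn$freq * times + theta + lag) * post
        }
      }
    }
  }

  if (!is.null(truth$kernel)) {
    K <- truth$kernel
    if (is.null(envelopes)) abort("truth$kernel requires envelopes")
    feats <- envelope_features(envelopes, fs)
    if (dim(K)[2] != nrow(feats[[1]])) {
      abort("kernel band count does not match the envelope feature bands")
    }
    if (dim(K)[1] != n_channels) abort("kernel channel count mismatch")
    n_post <- sum(post)
    for (tr in seq_len(n_trials)) {
      item <- feats[[(tr - 1) %% length(feats) + 1]]
      resp <- kernel_predict(K, item, n_post)
      data[tr, , post] <- data[tr, , post] + resp
    }
  }

  trial_tensor(data, fs, epoch_window, condition)
}

# channel x time linear response of kernel K (ch x band x lag) to
# band x time features, truncated/padded to n_time samples
kernel_predict <- function(K, feats, n_time) {
  n_ch <- dim(K)[1]; n_band <- dim(K)[2]; n_lag <- dim(K)[3]
  ft <- matrix(0, n_band, n_time)
  n_copy <- min(ncol(feats), n_time)
  ft[, seq_len(n_copy)] <- feats[, seq_len(n_copy)]
  out <- matrix(0, n_ch, n_time)
  for (lag in seq_len(n_lag)) {
    shifted <- cbind(matrix(0, n_band, lag - 1),
                     ft[, seq_len(n_time - lag + 1), drop = FALSE])
    out <- out + K[, , lag, drop = FALSE][, , 1] %*% shifted
  }
  out
}

# interpolate envelope-set items onto the trial sampling rate
envelope_features <- function(envelopes, fs) {
  if (inherits(envelopes, "envelope_set")) {
    items <- lapply(seq_len(nrow(envelopes$env)), function(i) {
      env_to_bands(envelopes$env[i, ], envelopes$fs, fs)
    })
    return(items)
  }
  if (is.matrix(envelopes)) return(list(envelopes))
  if (is.list(envelopes)) return(envelopes)
  abort("unsupported envelopes input")
}

# expand a broadband envelope into 16 pseudo-spectral bands by scaling with
# a fixed log-spaced gain profile (synthetic stand-in for a spectrogram)
env_to_bands <- function(env, fs_in, fs_out, n_bands = 16) {
  dur <- length(env) / fs_in
  t_out <- seq(0, dur - 1 / fs_out, by = 1 / fs_out)
  resampled <- approx(seq(0, dur - 1 / fs_in, by = 1 / fs_in), env,
                      xout = t_out, rule = 2)$y
  gains <- exp(-abs(log(seq_len(n_bands)) - log(n_bands / 3)))
  outer(gains, resampled)
}

#' Generate stationary null trials
#'
#' Pure white noise with no condition-dependent structure: any two random
#' splits satisfy the null hypothesis of every test in the package.
#'
#' @param n_trials Number of trials (>= 2).
#' @param n_channels Number of channels.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param epoch_window Epoch in seconds relative to onset.
#' @param noise_sd Noise SD.
#' @return A `trial_tensor`.
#' @export
gen_null_trials <- function(n_trials, n_channels, fs = 256, seed = 1,
                            epoch_window = c(-1, 2), noise_sd = 1) {
  if (n_trials < 2) abort("need at least 2 trials")
  set.seed(substream_seed(seed, "null_trials"))
  n_time <- round((epoch_window[2] - epoch_window[1]) * fs)
  data <- array(rnorm(n_trials * n_channels * n_time, sd = noise_sd),
                dim = c(n_trials, n_channels, n_time))
  trial_tensor(data, fs, epoch_window)
}

pink_noise <- function(n, sd) {
  white <- rnorm(n)
  f <- fft(white)
  freqs <- pmax(1, seq_len(n) - 1)
  shaped <- Re(fft(f / sqrt(freqs), inverse = TRUE) / n)
  shaped / stats::sd(shaped) * sd
}

#' Generate paired syllable-rhythm stimulus envelopes
#'
#' Amplitude envelopes at 400 Hz with `syllable_rate` Hann-windowed bursts
#' per second (durations 140-230 ms, the non-isochronous 4-7 Hz syllable
#' range), RMS-normalised to -16 dB full scale. Items come in phrase/sentence
#' pairs that share identical burst onsets and durations, so acoustic
#' matching holds by construction; per-item amplitude jitter keeps paired
#' envelopes similar but not identical.
#'
#' @param n_items Number of phrase/sentence pairs.
#' @param duration Item duration in seconds (> 0).
#' @param syllable_rate Bursts per second (> 0).
#' @param seed Integer seed.
#' @param fs Envelope sampling rate (default 400 Hz).
#' @param amp_jitter_sd SD of the per-burst amplitude factor shared within
#'   a pair (default 0.35, emulating natural syllable stress variation).
#' @param member_jitter_sd SD of the additional per-member amplitude jitter
#'   (default 0.05); keeps paired envelopes similar but not identical.
#' @return An `envelope_set`: list with `env` (item x time matrix,
#'   2 * n_items rows), `fs`, `condition`, `pair`, `rms_db`.
#' @export
gen_envelopes <- function(n_items, duration = 1, syllable_rate = 4, seed = 1,
                          fs = 400, amp_jitter_sd = 0.35,
                          member_jitter_sd = 0.05) {
  if (duration <= 0 || syllable_rate <= 0) {
    abort("duration and syllable_rate must be positive")
  }
  set.seed(substream_seed(seed, "envelopes"))
  n_time <- round(duration * fs)
  slot <- 1 / syllable_rate
  n_bursts <- floor(duration * syllable_rate)
  env <- matrix(0, 2 * n_items, n_time)
  condition <- rep(c("phrase", "sentence"), n_items)
  pair <- rep(seq_len(n_items), each = 2)
  for (i in seq_len(n_items)) {
    onsets <- durs <- amps <- numeric(n_bursts)
    for (b in seq_len(n_bursts)) {
      d <- runif(1, 0.140, min(0.230, slot))
      onset <- (b - 1) * slot + runif(1, 0, slot - d)
      onsets[b] <- onset; durs[b] <- d
      amps[b] <- max(0.2, 1 + rnorm(1, sd = amp_jitter_sd)) # shared in pair
    }
    for (member in 1:2) {
      row <- numeric(n_time)
      for (b in seq_len(n_bursts)) {
        idx0 <- round(onsets[b] * fs)
        len <- max(4, round(durs[b] * fs))
        len <- min(len, n_time - idx0)
        w <- hann_window(len) * amps[b] *
          max(0.2, 1 + rnorm(1, sd = member_jitter_sd))
        row[idx0 + seq_len(len)] <- row[idx0 + seq_len(len)] + w
      }
      env[2 * (i - 1) + member, ] <- rms_normalize(row, -16)
    }
  }
  structure(
    list(env = env, fs = fs, condition = condition, pair = pair, rms_db = -16),
    class = "envelope_set"
  )
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n)))

#' @export
print.envelope_set <- function(x, ...) {
  cat(sprintf("<envelope_set: %d items x %.2f s @ %g Hz, RMS %g dB>\n",
              nrow(x$env), ncol(x$env) / x$fs, x$fs, x$rms_db))
  invisible(x)
}
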