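# Morlet wavelet time-frequency decomposition.
#
# The bank spans 1-50 Hz in 70 logarithmically spaced steps; the number of
# cycles grows log-spaced from 3 to 30 matched index-wise to frequency, the
# usual trade of temporal resolution at low frequencies for spectral
# resolution at high ones. Wavelets are amplitude-normalised so a
# unit-amplitude sinusoid at a centre frequency yields coefficient
# magnitude 1 at every position in the bank.

#' Construct a Morlet wavelet bank
#'
#' @param n_freqs Number of frequencies (default 70).
#' @param freq_range Frequency span in Hz (default c(1, 50)).
#' @param cycle_range Wavelet cycles at the first and last frequency
#'   (default c(3, 30)); interpolated log-spaced in between.
#' @return A `wavelet_bank`: tibble with columns `freq` and `cycles`.
#' @export
wavelet_bank <- function(n_freqs = 70, freq_range = c(1, 50),
                         cycle_range = c(3, 30)) {
  stopifnot(n_freqs >= 1, all(freq_range > 0), all(cycle_range > 0))
  bank <- tibble::tibble(
    freq = exp(seq(log(freq_range[1]), log(freq_range[2]), length.out = n_freqs)),
    cycles = exp(seq(log(cycle_range[1]), log(cycle_range[2]), length.out = n_freqs))
  )
  class(bank) <- c("wavelet_bank", class(bank))
  bank
}

# Complex Morlet coefficients for signals in the columns of `mat`.
# Returns freq x time x signal array. FFT convolution, centred kernel.
morlet_convolve <- function(mat, fs, freqs, cycles) {
  mat <- as.matrix(mat)
  n_time <- nrow(mat)
  n_sig <- ncol(mat)
  # kernel half width: 3.5 SD of the widest (lowest-frequency) wavelet
  sigmas <- cycles / (2 * pi * freqs)
  half <- ceiling(3.5 * max(sigmas) * fs)
  n_conv <- stats::nextn(n_time + 2 * half, 2)
  pad <- rbind(mat, matrix(0, n_conv - n_time, n_sig))
  data_f <- mvfft(pad)
  out <- array(0i, dim = c(length(freqs), n_time, n_sig))
  tker <- (seq_len(n_conv) - 1) / fs
  tker <- ifelse(tker > n_conv / (2 * fs), tker - n_conv / fs, tker) # wrap-around time
  for (fi in seq_along(freqs)) {
    s <- sigmas[fi]
    w <- exp(2i * pi * freqs[fi] * tker) * exp(-tker^2 / (2 * s^2))
    # normalise so a unit-amplitude cosine at the centre frequency -> |coef| = 1
    w <- w * (2 / sum(exp(-tker^2 / (2 * s^2))))
    w_f <- fft(w)
    res <- mvfft(data_f * w_f, inverse = TRUE) / n_conv
    out[fi, , ] <- res[seq_len(n_time), , drop = FALSE]
  }
  out
}

#' Morlet wavelet transform of an epoched trial tensor
#'
#' Convolves every trial and channel with the complex wavelet bank.
#' Edge samples within 3 SD of the widest wavelet of each frequency are
#' flagged invalid in the `valid` attribute (freq x time logical) rather
#' than dropped.
#'
#' @param trials A `trial_tensor` (see [gen_trials()]).
#' @param bank A `wavelet_bank`; default [wavelet_bank()].
#' @return A `tfr_tensor`: complex array trial x channel x freq x time with
#'   attributes `freqs`, `times`, `fs`, `valid`.
#' @export
tfr_transform <- function(trials, bank = wavelet_bank()) {
  stopifnot(inherits(trials, "trial_tensor"))
  fs <- trials$fs
  if (fs < 2 * max(bank$freq)) abort("sampling rate below Nyquist for the bank")
  d <- dim(trials$data)
  n_trial <- d[1]; n_chan <- d[2]; n_time <- d[3]
  # stack trial/channel signals into columns
  mat <- matrix(0, n_time, n_trial * n_chan)
  for (tr in seq_len(n_trial)) {
    mat[, (tr - 1) * n_chan + seq_len(n_chan)] <- t(trials$data[tr, , ])
  }
  co <- morlet_convolve(mat, fs, bank$freq, bank$cycles)
  out <- array(0i, dim = c(n_trial, n_chan, nrow(bank), n_time))
  for (tr in seq_len(n_trial)) {
    out[tr, , , ] <- aperm(co[, , (tr - 1) * n_chan + seq_len(n_chan), drop = FALSE], c(3, 1, 2))
  }
  sigmas <- bank$cycles / (2 * pi * bank$freq)
  edge <- ceiling(3 * sigmas * fs)
  valid <- matrix(TRUE, nrow(bank), n_time)
  for (fi in seq_len(nrow(bank))) {
    k <- min(edge[fi], n_time)
    valid[fi, seq_len(k)] <- FALSE
    valid[fi, n_time - seq_len(k) + 1] <- FALSE
  }
  structure(
    list(
      coeffs = out, freqs = bank$freq, times = trials$times, fs = fs,
      valid = valid, onset_index = trials$onset_index
    ),
    class = "tfr_tensor"
  )
}

#' @export
print.tfr_tensor <- function(x, ...) {
  d <- dim(x$coeffs)
  cat(sprintf(
    "<tfr_tensor: %d trials x %d channels x %d freqs (%.2g-%.3g Hz) x %d samples @ %g Hz>\n",
    d[1], d[2], d[3], min(x$freqs), max(x$freqs), d[4], x$fs
  ))
  invisible(x)
}
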