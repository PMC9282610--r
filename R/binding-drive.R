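# Syllable-like drive sequences for the binding simulation.

#' Generate shared drive sequences for the binding simulation
#'
#' Builds `n_pairs` drives of four S-unit sequences each. A drive is
#' `duration` seconds long; within every second, S-unit k may fire only
#' inside the k-th 250-ms window, and fires exactly once as a rectangular
#' burst of random duration uniform in \[140, 230\] ms with a random onset
#' that keeps the burst inside its window — emulating the non-isochronous
#' 4–7 Hz syllable rhythm of natural speech. White Gaussian noise is added
#' and each sequence is normalised by pointwise division by its maximum.
#' The same drive is reused for the phrase and the sentence propagation of a
#' pair, so any downstream contrast isolates the structural difference.
#'
#' @param n_pairs Number of phrase/sentence drive pairs (default 100).
#' @param fs Sampling rate in Hz (>= 500; default 1000).
#' @param duration Sequence length in seconds (default 12).
#' @param noise_sd SD of the additive white noise, relative to the unit
#'   burst amplitude (default 0.2).
#' @param seed Integer seed; fully determines the output.
#' @return A `drive_set`: list with `sequences` (array pair x S-unit x time),
#'   `fs`, `duration`, `n_pairs`.
#' @export
gen_drive <- function(n_pairs = 100, fs = 1000, duration = 12, noise_sd = 0.2,
                      seed = 1) {
  if (fs < 500) abort("fs must be >= 500 Hz")
  if (duration <= 0 || n_pairs < 1) abort("invalid drive parameters")
  set.seed(substream_seed(seed, "drive"))
  n_time <- round(duration * fs)
  seqs <- array(0, dim = c(n_pairs, 4, n_time))
  win <- round(0.25 * fs)
  for (p in seq_len(n_pairs)) {
    for (k in 1:4) {
      x <- numeric(n_time)
      for (sec in seq_len(floor(duration))) {
        d <- round(runif(1, 0.140, 0.230) * fs)
        w0 <- (sec - 1) * fs + (k - 1) * win           # window start (0-based)
        onset <- w0 + sample.int(win - d + 1, 1) - 1L  # burst stays inside window
        x[(onset + 1):(onset + d)] <- 1
      }
      x <- x + rnorm(n_time, sd = noise_sd)
      seqs[p, k, ] <- peak_normalize(x)
    }
  }
  structure(
    list(sequences = seqs, fs = fs, duration = duration, n_pairs = n_pairs),
    class = "drive_set"
  )
}

#' @export
print.drive_set <- function(x, ...) {
  cat(sprintf(
    "<drive_set: %d pairs x 4 S-units x %.1f s @ %g Hz>\n",
    x$n_pairs, x$duration, x$fs
  ))
  invisible(x)
}
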