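# Epoched multichannel time-series container: trial x channel x time, with
# sampling rate and stimulus-onset index. The substrate of every analysis.

#' Construct an epoched trial tensor
#'
#' @param data Numeric array trial x channel x time; all values finite.
#' @param fs Sampling rate in Hz.
#' @param epoch_window Two-element numeric, epoch start/end in seconds
#'   relative to stimulus onset. At least 0.8 s of pre-onset baseline is
#'   required (the dB baseline window is -0.8 to -0.2 s).
#' @param condition Optional label per trial (recycled if length 1).
#' @return A `trial_tensor` object with elements `data`, `fs`,
#'   `onset_index`, `times`, `epoch_window`, `condition`.
#' @export
trial_tensor <- function(data, fs, epoch_window, condition = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3, fs > 0)
  if (!all(is.finite(data))) abort("trial data contain non-finite samples")
  if (length(epoch_window) != 2 || epoch_window[1] > epoch_window[2]) {
    abort("epoch_window must be c(start, end) in seconds")
  }
  if (epoch_window[1] > -0.8) {
    abort("epoch must contain at least 800 ms of pre-onset baseline")
  }
  n_time <- dim(data)[3]
  times <- epoch_window[1] + (seq_len(n_time) - 1) / fs
  onset_index <- which.min(abs(times))
  if (!is.null(condition)) {
    condition <- rep_len(as.character(condition), dim(data)[1])
  }
  structure(
    list(data = data, fs = fs, onset_index = onset_index, times = times,
         epoch_window = epoch_window, condition = condition),
    class = "trial_tensor"
  )
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<trial_tensor: %d trials x %d channels x %d samples @ %g Hz, epoch [%g, %g] s>\n",
    d[1], d[2], d[3], x$fs, x$epoch_window[1], x$epoch_window[2]
  ))
  if (!is.null(x$condition)) {
    cat("  conditions:", paste(unique(x$condition), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.trial_tensor <- function(x) dim(x$data)

# Index range of a time window (seconds relative to onset), inclusive.
time_window_idx <- function(times, window) {
  idx <- which(times >= window[1] & times <= window[2])
  if (!length(idx)) abort("time window outside epoch")
  idx
}

#' Write a trial tensor to a CSV file
#'
#' Long format: trial, channel, time, value (plus condition if present).
#'
#' @param x A `trial_tensor`.
#' @param path Output file path.
#' @export
write_trial_tensor_csv <- function(x, path) {
  stopifnot(inherits(x, "trial_tensor"))
  d <- dim(x$data)
  df <- data.frame(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    time = rep(x$times, each = d[1] * d[2]),
    value = as.vector(x$data)
  )
  if (!is.null(x$condition)) df$condition <- x$condition[df$trial]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
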