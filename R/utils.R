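# Shared numerical helpers. Everything here is deterministic and seed-free;
# randomness always enters through an explicit `seed` argument of the caller.

#' Analytic signal via the FFT Hilbert method
#'
#' Returns the complex analytic representation `x + i * H(x)` of a real
#' signal, computed by zeroing negative frequencies in the DFT. Works
#' column-wise on matrices.
#'
#' @param x Numeric vector or matrix (signals in columns).
#' @return Complex vector/matrix of the same shape.
#' @export
analytic_signal <- function(x) {
  if (is.matrix(x)) {
    return(apply(x, 2, analytic_signal))
  }
  n <- length(x)
  if (n == 0) abort("empty signal")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Mean resultant length of a set of phases
#'
#' The magnitude of the average of unit phasors; 1 means perfect phase
#' alignment, 0 a balanced (e.g. uniform) phase distribution.
#'
#' @param z Complex vector of (not necessarily unit) phasors, or numeric
#'   vector of phase angles in radians.
#' @param na.rm Drop missing values before averaging.
#' @return Scalar in \[0, 1\].
#' @export
resultant_length <- function(z, na.rm = FALSE) {
  if (is.numeric(z)) z <- exp(1i * z)
  zu <- z / Mod(z)
  Mod(mean(zu, na.rm = na.rm))
}

# Causal moving average with implicit zero padding before the signal:
# y[t] = mean(x[max(1, t-L+1) .. t]) with x[s] = 0 for s < 1.
causal_moving_average <- function(x, width) {
  stopifnot(width >= 1)
  cs <- cumsum(x)
  lagged <- c(rep(0, width), head(cs, -width))[seq_along(x)]
  (cs - lagged) / width
}

# Zero-phase FIR low-pass (windowed sinc designed by signal::fir1, applied
# forward-backward). Order defaults to 3 * fs / cutoff, forced even.
lowpass_zero_phase <- function(x, fs, cutoff, order = NULL) {
  stopifnot(cutoff > 0, cutoff < fs / 2)
  if (is.null(order)) order <- round(3 * fs / cutoff)
  order <- max(4L, as.integer(order))
  if (order %% 2 == 1) order <- order + 1L
  b <- as.numeric(signal::fir1(order, cutoff / (fs / 2), type = "low"))
  as.numeric(signal::filtfilt(filt = b, a = 1, x = x))
}

# Peak normalization guarded for all-zero signals.
peak_normalize <- function(x) {
  m <- max(abs(x))
  if (m == 0) x else x / m
}

# Deterministic child seed streams: one independent stream per named stage,
# all below 2^31.
substream_seed <- function(seed, k) {
  if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483629)
}

# RMS of a signal relative to full scale 1.
signal_rms <- function(x) sqrt(mean(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
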