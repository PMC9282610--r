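# Measures derived from the wavelet coefficient tensor: intertrial phase
# coherence, induced power with decibel baselining, and frequency tagging
# of concatenated responses.

#' Intertrial phase coherence
#'
#' At every channel/frequency/time bin the complex coefficients of all
#' trials are divided by their magnitude and averaged; the magnitude of the
#' average is the ITPC (1 = identical phase across trials, 0 = balanced
#' phases). Zero-magnitude coefficients are treated as missing, not as
#' phase zero.
#'
#' @param tfr A `tfr_tensor` from [tfr_transform()].
#' @return An `itpc_map`: list with `values` (channel x freq x time, in
#'   \[0,1\] or NA), `freqs`, `times`.
#' @export
itpc <- function(tfr) {
  stopifnot(inherits(tfr, "tfr_tensor"))
  co <- tfr$coeffs
  if (dim(co)[1] < 2) abort("ITPC needs at least 2 trials")
  m <- Mod(co)
  u <- co / m
  u[m == 0] <- NA_complex_
  vals <- apply(u, c(2, 3, 4), function(z) {
    if (all(is.na(z))) NA_real_ else Mod(mean(z, na.rm = TRUE))
  })
  structure(list(values = vals, freqs = tfr$freqs, times = tfr$times,
                 kind = "itpc"),
            class = c("itpc_map", "tf_map"))
}

#' Induced power in decibels relative to a pre-onset baseline
#'
#' Power (squared coefficient magnitude averaged over trials) is converted,
#' separately per channel and frequency, to `10 * log10(power / baseline)`
#' where the baseline is the mean power in `baseline_window`.
#'
#' @param tfr A `tfr_tensor`.
#' @param baseline_window Two-element window in seconds relative to onset
#'   (default c(-0.8, -0.2)).
#' @return A `power_map`: list with `values` (channel x freq x time, dB),
#'   `raw` (linear power), `freqs`, `times`.
#' @export
induced_power <- function(tfr, baseline_window = c(-0.8, -0.2)) {
  stopifnot(inherits(tfr, "tfr_tensor"))
  pw <- apply(Mod(tfr$coeffs)^2, c(2, 3, 4), mean)
  bidx <- time_window_idx(tfr$times, baseline_window)
  base <- apply(pw[, , bidx, drop = FALSE], c(1, 2), mean)
  if (any(base == 0)) abort("zero baseline power; dB baseline undefined")
  db <- array(0, dim(pw))
  for (ch in seq_len(dim(pw)[1])) {
    db[ch, , ] <- 10 * log10(pw[ch, , ] / base[ch, ])
  }
  structure(list(values = db, raw = pw, freqs = tfr$freqs, times = tfr$times,
                 baseline_window = baseline_window, kind = "power_db"),
            class = c("power_map", "tf_map"))
}

#' @export
print.tf_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s: %d channels x %d freqs x %d samples>\n",
              class(x)[1], d[1], d[2], d[3]))
  invisible(x)
}

#' Long-format view of a channel x frequency x time map
#'
#' @param x An `itpc_map` or `power_map`.
#' @param ... Unused.
#' @return Tibble with channel, freq, time, value.
#' @export
tidy.tf_map <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(
    channel = rep(seq_len(d[1]), times = d[2] * d[3]),
    freq = rep(rep(x$freqs, each = d[1]), times = d[3]),
    time = rep(x$times, each = d[1] * d[2]),
    value = as.vector(x$values)
  )
}

#' Time-frequency heat map of an ITPC or power map
#'
#' @param object An `itpc_map` or `power_map`.
#' @param channel Channel to plot (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tf_map <- function(object, channel = 1, ...) {
  df <- dplyr::filter(tidy(object), .data$channel == !!channel)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = object$kind) +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Frequency tagging of concatenated responses
#'
#' Concatenates randomly drawn 1-s post-onset responses into
#' `concat_len`-second trials, computes their DFT amplitude spectra
#' (averaged over channels), expresses them in dB relative to equally
#' constructed pre-onset baseline concatenations, and tests each tag
#' frequency against the mean of `flank_bins` neighbouring bins on each
#' side with a paired t test across the concatenated trials.
#'
#' @param trials A `trial_tensor` whose epoch covers \[-1, 1\] s or more.
#' @param concat_len Concatenation length in seconds (integer; default 15).
#' @param n_trials_out Number of concatenated trials (default 40).
#' @param flank_bins Flanking bins per side for the peak test (default 5).
#' @param tags Tag frequencies in Hz (default c(1, 4)).
#' @param seed Integer seed for the random draws.
#' @return A `freq_tagging` object: list with `spectrum` tibble
#'   (freq, mean_db, se_db) and `tests` tibble (tag, t, df, p.value).
#' @export
frequency_tagging <- function(trials, concat_len = 15, n_trials_out = 40,
                              flank_bins = 5, tags = c(1, 4), seed = 1) {
  stopifnot(inherits(trials, "trial_tensor"))
  if (abs(concat_len - round(concat_len)) > 1e-9) {
    abort("concat_len must be a whole number of 1-s epochs")
  }
  concat_len <- as.integer(round(concat_len))
  fs <- trials$fs
  n_seg <- round(fs) # 1-s segment length in samples
  post_idx <- which(trials$times >= 0)[seq_len(n_seg)]
  pre_idx <- rev(which(trials$times < 0))[seq_len(n_seg)] |> rev()
  if (anyNA(post_idx) || anyNA(pre_idx)) {
    abort("epoch must contain a full second before and after onset")
  }
  n_trials <- dim(trials$data)[1]
  set.seed(substream_seed(seed, "freq_tagging"))
  n_bins <- concat_len * n_seg
  freqs <- (seq_len(n_bins) - 1) / concat_len
  amp_post <- amp_pre <- matrix(0, n_trials_out, n_bins)
  # Sampling plan, most independent the pool allows. Reusing the same 1-s
  # epochs across (or within) concatenations adds a shared component at
  # integer-Hz bins — exactly the tag bins — which breaks the exchangeability
  # the across-concatenation t test needs, so: disjoint partition when the
  # pool covers all concatenations; else without replacement per
  # concatenation; else with replacement.
  if (n_trials >= concat_len * n_trials_out) {
    perm <- sample.int(n_trials, concat_len * n_trials_out)
    draw_sets <- split(perm, rep(seq_len(n_trials_out), each = concat_len))
  } else {
    draw_sets <- lapply(seq_len(n_trials_out), function(i) {
      sample.int(n_trials, concat_len, replace = concat_len > n_trials)
    })
  }
  for (i in seq_len(n_trials_out)) {
    draw <- draw_sets[[i]]
    n_ch <- dim(trials$data)[2]
    seg_post <- unlist(lapply(draw, function(tr) {
      colMeans(matrix(trials$data[tr, , post_idx], nrow = n_ch))
    }))
    seg_pre <- unlist(lapply(draw, function(tr) {
      colMeans(matrix(trials$data[tr, , pre_idx], nrow = n_ch))
    }))
    amp_post[i, ] <- Mod(fft(seg_post)) / n_bins
    amp_pre[i, ] <- Mod(fft(seg_pre)) / n_bins
  }
  # each concatenation is referenced to its own baseline-stage spectrum,
  # keeping concatenations statistically independent of one another
  db <- 20 * log10(pmax(amp_post, .Machine$double.eps) /
                     pmax(amp_pre, .Machine$double.eps))
  keep <- seq_len(floor(n_bins / 2))
  tests <- dplyr::bind_rows(lapply(tags, function(f0) {
    bin <- which.min(abs(freqs[keep] - f0))
    flanks <- c(bin - seq_len(flank_bins), bin + seq_len(flank_bins))
    flanks <- flanks[flanks >= 1 & flanks <= length(keep)]
    tt <- t.test(db[, bin], rowMeans(db[, flanks, drop = FALSE]), paired = TRUE)
    tibble::tibble(tag = f0, bin_freq = freqs[bin],
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p.value = tt$p.value)
  }))
  spectrum <- tibble::tibble(
    freq = freqs[keep],
    mean_db = colMeans(db[, keep, drop = FALSE]),
    se_db = apply(db[, keep, drop = FALSE], 2, sd) / sqrt(n_trials_out)
  )
  structure(list(spectrum = spectrum, tests = tests,
                 concat_len = concat_len),
            class = "freq_tagging")
}

#' @export
print.freq_tagging <- function(x, ...) {
  cat(sprintf("<freq_tagging: %d-s concatenations>\n", x$concat_len))
  print(x$tests)
  invisible(x)
}

#' @export
tidy.freq_tagging <- function(x, ...) x$tests

#' Spectrum plot of a frequency-tagging result
#'
#' @param object A `freq_tagging` object.
#' @param max_freq Upper frequency limit of the plot (default 8 Hz).
#' @param ... Unused.
#' @export
autoplot.freq_tagging <- function(object, max_freq = 8, ...) {
  df <- dplyr::filter(object$spectrum, .data$freq > 0, .data$freq <= max_freq)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$mean_db)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$tests$tag, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "frequency (Hz)", y = "response (dB re baseline)") +
    ggplot2::theme_minimal()
}
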