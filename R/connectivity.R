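# All-to-all sensor connectivity: intersite phase clustering (phase kind)
# and trial-wise rank correlation of power (power kind), thresholded into
# binary graphs, degree maps and baseline-normalised degree change.

#' Intersite phase clustering across all channel pairs
#'
#' Per channel pair, frequency and time bin: the cross-spectral density of
#' the two channels' wavelet coefficients is magnitude-normalised per trial
#' and averaged over trials; its magnitude is the ISPC. Zero-magnitude CSD
#' bins are treated as missing.
#'
#' @param tfr A `tfr_tensor` with >= 2 trials.
#' @return A `connectivity_stack`: list with `values` (channel x channel x
#'   freq x time, symmetric, diagonal NA), `kind = "phase"`, `freqs`,
#'   `times`.
#' @export
ispc <- function(tfr) {
  stopifnot(inherits(tfr, "tfr_tensor"))
  co <- tfr$coeffs
  d <- dim(co)
  if (d[1] < 2) abort("ISPC needs at least 2 trials")
  n_ch <- d[2]
  vals <- array(NA_real_, dim = c(n_ch, n_ch, d[3], d[4]))
  for (a in seq_len(n_ch - 1)) {
    for (b in (a + 1):n_ch) {
      csd <- co[, a, , , drop = FALSE] * Conj(co[, b, , , drop = FALSE])
      m <- Mod(csd)
      u <- csd / m
      u[m == 0] <- NA_complex_
      v <- apply(u, c(3, 4), function(z) {
        if (all(is.na(z))) NA_real_ else Mod(mean(z, na.rm = TRUE))
      })
      vals[a, b, , ] <- v
      vals[b, a, , ] <- v
    }
  }
  structure(list(values = vals, kind = "phase", freqs = tfr$freqs,
                 times = tfr$times),
            class = "connectivity_stack")
}

#' Rank-correlation power connectivity across all channel pairs
#'
#' Per channel pair, frequency and time bin: Spearman correlation across
#' trials between the two channels' single-trial power values. Constant
#' power across trials makes the correlation undefined; such bins are
#' missing.
#'
#' @param power Trial-resolved power array (trial x channel x freq x time),
#'   e.g. `Mod(tfr$coeffs)^2`, or a `tfr_tensor` (power taken internally).
#' @param freqs,times Axis vectors, taken from the `tfr_tensor` if one is
#'   supplied.
#' @return A `connectivity_stack` with `kind = "power"`, values in
#'   \[-1, 1\].
#' @export
power_connectivity <- function(power, freqs = NULL, times = NULL) {
  if (inherits(power, "tfr_tensor")) {
    freqs <- power$freqs; times <- power$times
    power <- Mod(power$coeffs)^2
  }
  d <- dim(power)
  if (d[1] < 3) abort("power connectivity needs at least 3 trials")
  n_ch <- d[2]
  vals <- array(NA_real_, dim = c(n_ch, n_ch, d[3], d[4]))
  for (fi in seq_len(d[3])) {
    for (ti in seq_len(d[4])) {
      x <- power[, , fi, ti] # trials x channels
      const <- apply(x, 2, function(v) length(unique(v)) == 1)
      suppressWarnings(r <- cor(x, method = "spearman"))
      r[const, ] <- NA_real_
      r[, const] <- NA_real_
      diag(r) <- NA_real_
      vals[, , fi, ti] <- r
    }
  }
  structure(list(values = vals, kind = "power", freqs = freqs, times = times),
            class = "connectivity_stack")
}

#' @export
print.connectivity_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<connectivity_stack (%s): %d x %d channels x %d freqs x %d samples>\n",
              x$kind, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Threshold two connectivity stacks into binary graphs and degree maps
#'
#' At every frequency-time bin the upper-triangle values of BOTH conditions
#' are pooled; the threshold is the pooled median plus half the pooled SD.
#' Each condition's matrix is binarised at strictly-greater-than the
#' threshold; the degree is the super-threshold count (global, and per
#' channel), finally expressed as percent change relative to the mean
#' degree in `baseline_window`.
#'
#' @param stack_a,stack_b `connectivity_stack`s of identical shape
#'   (condition A and B).
#' @param baseline_window Seconds relative to onset (default
#'   c(-0.8, -0.2)); set `NULL` to skip percent-change conversion.
#' @return A `degree_map`: list with per-condition `count` (freq x time
#'   global counts), `channel_count` (channel x freq x time), binary
#'   matrices `binary` (channel x channel x freq x time, logical),
#'   `percent_change` (freq x time, or NULL), and `threshold` (freq x time).
#' @export
threshold_degree <- function(stack_a, stack_b, baseline_window = c(-0.8, -0.2)) {
  stopifnot(inherits(stack_a, "connectivity_stack"),
            inherits(stack_b, "connectivity_stack"))
  if (!identical(dim(stack_a$values), dim(stack_b$values))) {
    abort("conditions must have the same shape")
  }
  d <- dim(stack_a$values)
  n_ch <- d[1]
  ut <- upper.tri(matrix(0, n_ch, n_ch))
  thr <- matrix(NA_real_, d[3], d[4])
  out <- lapply(c(a = 1, b = 2), function(i) {
    list(count = matrix(NA_real_, d[3], d[4]),
         channel_count = array(NA_real_, c(n_ch, d[3], d[4])),
         binary = array(NA, c(n_ch, n_ch, d[3], d[4])))
  })
  stacks <- list(stack_a$values, stack_b$values)
  for (fi in seq_len(d[3])) {
    for (ti in seq_len(d[4])) {
      pool <- c(stacks[[1]][, , fi, ti][ut], stacks[[2]][, , fi, ti][ut])
      pool <- pool[!is.na(pool)]
      if (!length(pool)) abort("empty pooled connectivity distribution")
      thr[fi, ti] <- median(pool) + 0.5 * sd_or_zero(pool)
      for (i in 1:2) {
        m <- stacks[[i]][, , fi, ti]
        bin <- !is.na(m) & m > thr[fi, ti]
        diag(bin) <- FALSE
        out[[i]]$binary[, , fi, ti] <- bin
        out[[i]]$count[fi, ti] <- sum(bin[ut])
        out[[i]]$channel_count[, fi, ti] <- rowSums(bin)
      }
    }
  }
  pc <- NULL
  if (!is.null(baseline_window)) {
    bidx <- time_window_idx(stack_a$times, baseline_window)
    pc <- lapply(1:2, function(i) {
      base <- rowMeans(out[[i]]$count[, bidx, drop = FALSE])
      chg <- 100 * sweep(out[[i]]$count, 1, base, `-`)
      chg <- sweep(chg, 1, base, `/`)
      chg[base == 0, ] <- NA_real_
      chg
    })
    names(pc) <- c("a", "b")
  }
  structure(
    list(count = list(a = out[[1]]$count, b = out[[2]]$count),
         channel_count = list(a = out[[1]]$channel_count, b = out[[2]]$channel_count),
         binary = list(a = out[[1]]$binary, b = out[[2]]$binary),
         percent_change = pc, threshold = thr,
         freqs = stack_a$freqs, times = stack_a$times, n_channels = n_ch),
    class = "degree_map"
  )
}

sd_or_zero <- function(x) if (length(x) < 2) 0 else sd(x)

#' @export
print.degree_map <- function(x, ...) {
  cat(sprintf("<degree_map: %d channels, %d freqs x %d bins>\n",
              x$n_channels, length(x$freqs), length(x$times)))
  invisible(x)
}

#' Long-format view of a degree map
#'
#' @param x A `degree_map`.
#' @param ... Unused.
#' @return Tibble with condition, freq, time, count, percent_change,
#'   threshold.
#' @export
tidy.degree_map <- function(x, ...) {
  grid <- tidyr::expand_grid(
    condition = c("a", "b"),
    fi = seq_along(x$freqs), ti = seq_along(x$times)
  )
  dplyr::mutate(
    grid,
    freq = x$freqs[.data$fi], time = x$times[.data$ti],
    count = purrr::pmap_dbl(list(.data$condition, .data$fi, .data$ti),
                            function(cd, f, t) x$count[[cd]][f, t]),
    percent_change = if (is.null(x$percent_change)) NA_real_ else
      purrr::pmap_dbl(list(.data$condition, .data$fi, .data$ti),
                      function(cd, f, t) x$percent_change[[cd]][f, t]),
    threshold = x$threshold[cbind(.data$fi, .data$ti)]
  )[c("condition", "freq", "time", "count", "percent_change", "threshold")]
}

#' Seed-based connection profiles from binarised matrices
#'
#' Average binary connection strength from a seed channel set to every
#' channel, per condition, averaged over the selected frequency-time bins.
#'
#' @param degree A `degree_map` from [threshold_degree()].
#' @param seeds Integer vector of seed channel indices (non-empty).
#' @param freq_idx,time_idx Bin selections (default all).
#' @return Tibble with condition, channel, profile (mean binary connection
#'   to the seed set).
#' @export
seed_connectivity <- function(degree, seeds, freq_idx = NULL, time_idx = NULL) {
  if (is.matrix(degree)) { # plain binary/weight matrix: mean of the seed rows
    if (!length(seeds)) abort("empty seed set")
    if (any(seeds < 1 | seeds > nrow(degree))) abort("invalid seed channel")
    return(tibble::tibble(
      condition = "a", channel = seq_len(ncol(degree)),
      profile = colMeans(degree[seeds, , drop = FALSE])
    ))
  }
  stopifnot(inherits(degree, "degree_map"))
  if (!length(seeds)) abort("empty seed set")
  if (any(seeds < 1 | seeds > degree$n_channels)) abort("invalid seed channel")
  freq_idx <- freq_idx %||% seq_along(degree$freqs)
  time_idx <- time_idx %||% seq_along(degree$times)
  dplyr::bind_rows(lapply(c("a", "b"), function(cd) {
    b <- degree$binary[[cd]][, , freq_idx, time_idx, drop = FALSE]
    prof <- apply(b[seeds, , , , drop = FALSE], 2, mean)
    tibble::tibble(condition = cd, channel = seq_len(degree$n_channels),
                   profile = prof)
  }))
}

#' Select the k strongest channels of a metric map per hemisphere
#'
#' Generic ROI utility: given per-channel metric values and a hemisphere
#' assignment, returns the `k` channels with the largest (or smallest)
#' metric in each hemisphere.
#'
#' @param metric Named or plain numeric vector, one value per channel.
#' @param k Channels to keep per hemisphere.
#' @param hemisphere Vector (`"left"`/`"right"`/other) per channel.
#' @param decreasing Take largest values (default TRUE; set FALSE for
#'   strongest inhibition).
#' @return Tibble with channel, hemisphere, metric, ordered by hemisphere.
#' @export
select_top_channels <- function(metric, k, hemisphere, decreasing = TRUE) {
  stopifnot(length(metric) == length(hemisphere), k >= 1)
  df <- tibble::tibble(channel = seq_along(metric), hemisphere = hemisphere,
                       metric = as.numeric(metric))
  df <- dplyr::group_by(df, .data$hemisphere)
  df <- dplyr::slice_max(df, order_by = if (decreasing) .data$metric else -.data$metric,
                         n = k, with_ties = FALSE)
  dplyr::ungroup(df)
}
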