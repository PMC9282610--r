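# Spectrotemporal response function estimation: 16-band envelope features,
# bootstrap construction of stimulus-response pairs, ridge regression with
# leave-one-pair-out cross-validation over a lambda grid, matched-vs-random
# performance, and TRF/SRF decomposition with peak and band statistics.

#' 16-band spectrogram features of an audio waveform
#'
#' Band-pass filters the waveform into 16 logarithmically spaced bands
#' spanning 0.05-8 kHz, extracts each band's Hilbert envelope, and
#' resamples to the neural sampling rate.
#'
#' @param audio Mono numeric waveform.
#' @param fs_in Input sampling rate in Hz (e.g. 44100).
#' @param target_fs Output (neural) sampling rate in Hz.
#' @param n_bands Number of bands (default 16).
#' @param band_range Band span in Hz (default c(50, 8000)).
#' @return A `spectrogram_feature`: list with `envelopes` (band x time),
#'   `band_edges`, `band_centers`, `fs`.
#' @export
spectrogram_features <- function(audio, fs_in, target_fs, n_bands = 16,
                                 band_range = c(50, 8000)) {
  if (!is.numeric(audio) || !all(is.finite(audio))) abort("audio must be finite numeric")
  band_range[2] <- min(band_range[2], 0.45 * fs_in)
  edges <- exp(seq(log(band_range[1]), log(band_range[2]), length.out = n_bands + 1))
  centers <- sqrt(edges[-1] * edges[-(n_bands + 1)])
  n_out <- round(length(audio) / fs_in * target_fs)
  env <- matrix(0, n_bands, n_out)
  if (any(audio != 0)) {
    for (b in seq_len(n_bands)) {
      bf <- signal::butter(4, c(edges[b], edges[b + 1]) / (fs_in / 2), type = "pass")
      xb <- as.numeric(signal::filtfilt(bf, audio))
      e <- Mod(analytic_signal(xb))
      env[b, ] <- resample_envelope(e, fs_in, target_fs, n_out)
    }
  }
  structure(list(envelopes = env, band_edges = edges, band_centers = centers,
                 fs = target_fs),
            class = "spectrogram_feature")
}

# anti-aliased downsampling of a non-negative envelope
resample_envelope <- function(e, fs_in, fs_out, n_out) {
  if (fs_out < fs_in) {
    cutoff <- 0.4 * fs_out
    if (cutoff < fs_in / 2) e <- lowpass_zero_phase(e, fs_in, cutoff)
  }
  t_in <- (seq_along(e) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  pmax(0, approx(t_in, e, xout = t_out, rule = 2)$y)
}

#' Build bootstrap train/test stimulus-response pair sets
#'
#' Splits the unique stimuli into a training fraction and a held-out test
#' fraction (no stimulus appears in both), then builds `n_train` training
#' pairs, each a concatenation of `train_len` randomly drawn (with
#' replacement) 1-s stimulus-response pairs from the training split, and
#' `n_test` test pairs of `test_len` seconds from the held-out split.
#'
#' @param features List of band x time feature matrices, one per stimulus
#'   (all at the neural sampling rate, equal 1-s length).
#' @param responses List of channel x time response matrices matched to
#'   `features`.
#' @param train_frac Fraction of unique stimuli for training (default 0.8).
#' @param n_train,n_test Number of training/test pairs (defaults 35, 5).
#' @param train_len,test_len Pair lengths in seconds (defaults 10, 4).
#' @param ramp_frac Linear onset/offset ramp applied to each 1-s response
#'   (default 0.1 per side).
#' @param seed Integer seed.
#' @return A `pair_set` tibble: pair_id, role ("train"/"test"), stimuli
#'   (list of stimulus ids), features (list of band x time), response
#'   (list of channel x time).
#' @export
build_pairs <- function(features, responses, train_frac = 0.8, n_train = 35,
                        train_len = 10, n_test = 5, test_len = 4,
                        ramp_frac = 0.1, seed = 1) {
  n_stim <- length(features)
  if (n_stim < 10) abort("need at least 10 unique stimuli")
  if (length(responses) != n_stim) abort("features/responses length mismatch")
  set.seed(substream_seed(seed, "pairs"))
  n_tr <- round(train_frac * n_stim)
  train_ids <- sort(sample.int(n_stim, n_tr))
  test_ids <- setdiff(seq_len(n_stim), train_ids)
  stopifnot(length(intersect(train_ids, test_ids)) == 0)
  responses <- lapply(responses, ramp_response, ramp_frac = ramp_frac)
  mk <- function(ids, n_pairs, len, role, offset) {
    lapply(seq_len(n_pairs), function(i) {
      draw <- ids[sample.int(length(ids), len, replace = TRUE)]
      list(
        pair_id = offset + i, role = role, stimuli = draw,
        features = do.call(cbind, features[draw]),
        response = do.call(cbind, responses[draw])
      )
    })
  }
  rows <- c(mk(train_ids, n_train, train_len, "train", 0),
            mk(test_ids, n_test, test_len, "test", n_train))
  out <- tibble::tibble(
    pair_id = vapply(rows, `[[`, numeric(1), "pair_id"),
    role = vapply(rows, `[[`, character(1), "role"),
    stimuli = lapply(rows, `[[`, "stimuli"),
    features = lapply(rows, `[[`, "features"),
    response = lapply(rows, `[[`, "response")
  )
  attr(out, "train_ids") <- train_ids
  attr(out, "test_ids") <- test_ids
  class(out) <- c("pair_set", class(out))
  out
}

ramp_response <- function(resp, ramp_frac = 0.1) {
  n <- ncol(resp)
  k <- max(1, round(ramp_frac * n))
  ramp <- rep(1, n)
  ramp[seq_len(k)] <- seq(0, 1, length.out = k)
  ramp[n - seq_len(k) + 1] <- seq(0, 1, length.out = k)
  sweep(resp, 2, ramp, `*`)
}

# lagged design matrix: time x (band*lag), lag 0 first, causal
lagged_design <- function(feats, n_lags) {
  n_band <- nrow(feats); n_time <- ncol(feats)
  X <- matrix(0, n_time, n_band * n_lags)
  for (l in seq_len(n_lags)) {
    cols <- (l - 1) * n_band + seq_len(n_band)
    X[l:n_time, cols] <- t(feats[, 1:(n_time - l + 1), drop = FALSE])
  }
  X
}

#' Fit a spectrotemporal response function by ridge regression
#'
#' For every lambda on the grid, leave-one-pair-out cross-validation:
#' the model is fit on all but one training pair and evaluated on the
#' held-out pair as the Pearson correlation between predicted and actual
#' response, averaged over channels; performance per lambda is the average
#' over folds. The returned model is refit on all training pairs at the
#' best lambda. Features are z-scored per band on training statistics.
#'
#' @param pairs A `pair_set` from [build_pairs()] (training rows used).
#' @param fs Sampling rate of features/responses in Hz.
#' @param lag_window Kernel lag span in seconds (default c(0, 0.5)).
#' @param lambda_grid Ridge penalties (default 10 linear values 6-100).
#' @return An `strf_model`: list with `weights` (channel x band x lag),
#'   `intercept`, `lambda`, `cv` tibble (lambda, mean_r), `lags` (s),
#'   `feature_means`, `feature_sds`, `fs`.
#' @export
fit_strf <- function(pairs, fs, lag_window = c(0, 0.5),
                     lambda_grid = seq(6, 100, length.out = 10)) {
  train <- pairs[pairs$role == "train", ]
  if (nrow(train) < 3) abort("need at least 3 training pairs")
  if (lag_window[1] < 0) abort("kernel lags must be non-negative (causal)")
  n_lags <- round((lag_window[2] - lag_window[1]) * fs) + 1
  n_band <- nrow(train$features[[1]])
  # training z-scoring statistics per band
  allf <- do.call(cbind, train$features)
  fmu <- rowMeans(allf)
  fsd <- apply(allf, 1, sd); fsd[fsd == 0] <- 1
  folds <- lapply(seq_len(nrow(train)), function(i) {
    feats <- (train$features[[i]] - fmu) / fsd
    X <- lagged_design(feats, n_lags)
    Y <- t(train$response[[i]])
    list(XtX = crossprod(X), XtY = crossprod(X, Y), X = X, Y = Y,
         n = nrow(X), xbar = colMeans(X), ybar = colMeans(Y))
  })
  # centred accumulation so the intercept is handled exactly
  tot_XtX <- Reduce(`+`, lapply(folds, `[[`, "XtX"))
  tot_XtY <- Reduce(`+`, lapply(folds, `[[`, "XtY"))
  p <- ncol(folds[[1]]$XtX)
  cv <- vapply(lambda_grid, function(lam) {
    rs <- vapply(seq_along(folds), function(i) {
      XtX <- tot_XtX - folds[[i]]$XtX
      XtY <- tot_XtY - folds[[i]]$XtY
      B <- solve(XtX + diag(lam, p), XtY)
      pred <- folds[[i]]$X %*% B
      mean(vapply(seq_len(ncol(B)), function(ch) {
        suppressWarnings(r <- cor(pred[, ch], folds[[i]]$Y[, ch]))
        if (is.na(r)) 0 else r
      }, numeric(1)))
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  best <- which.max(cv)
  lam <- lambda_grid[best]
  B <- solve(tot_XtX + diag(lam, p), tot_XtY)
  n_ch <- ncol(B)
  W <- array(0, dim = c(n_ch, n_band, n_lags))
  for (l in seq_len(n_lags)) {
    W[, , l] <- t(B[(l - 1) * n_band + seq_len(n_band), , drop = FALSE])
  }
  # intercept from overall means
  xbar <- colMeans(do.call(rbind, lapply(folds, function(f) f$X)))
  ybar <- colMeans(do.call(rbind, lapply(folds, `[[`, "Y")))
  intercept <- ybar - as.vector(t(B) %*% xbar)
  structure(
    list(weights = W, intercept = intercept, lambda = lam,
         cv = tibble::tibble(lambda = lambda_grid, mean_r = cv),
         lags = lag_window[1] + (seq_len(n_lags) - 1) / fs,
         feature_means = fmu, feature_sds = fsd, fs = fs,
         lambda_grid = lambda_grid),
    class = "strf_model"
  )
}

#' @export
print.strf_model <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf(
    "<strf_model: %d channels x %d bands x %d lags (0-%.0f ms), lambda = %.3g>\n",
    d[1], d[2], d[3], 1000 * max(x$lags), x$lambda
  ))
  invisible(x)
}

#' Kernel weights of an STRF model in long format
#'
#' @param x An `strf_model`.
#' @param ... Unused.
#' @return Tibble with channel, band, lag (s), weight.
#' @export
tidy.strf_model <- function(x, ...) {
  d <- dim(x$weights)
  tibble::tibble(
    channel = rep(seq_len(d[1]), times = d[2] * d[3]),
    band = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    lag = rep(x$lags, each = d[1] * d[2]),
    weight = as.vector(x$weights)
  )
}

#' One-row summary of an STRF model fit
#'
#' @param x An `strf_model`.
#' @param ... Unused.
#' @export
glance.strf_model <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda,
    cv_r = max(x$cv$mean_r),
    n_channels = dim(x$weights)[1],
    n_bands = dim(x$weights)[2],
    n_lags = dim(x$weights)[3]
  )
}

#' Predict responses from an STRF model
#'
#' @param object An `strf_model`.
#' @param features Band x time feature matrix.
#' @param ... Unused.
#' @return Channel x time predicted response.
#' @export
predict.strf_model <- function(object, features, ...) {
  feats <- (features - object$feature_means) / object$feature_sds
  X <- lagged_design(feats, dim(object$weights)[3])
  n_band <- dim(object$weights)[2]
  B <- matrix(0, ncol(X), dim(object$weights)[1])
  for (l in seq_len(dim(object$weights)[3])) {
    B[(l - 1) * n_band + seq_len(n_band), ] <- t(object$weights[, , l])
  }
  t(X %*% B + rep(1, nrow(X)) %o% object$intercept)
}

#' Matched vs random performance of an STRF model
#'
#' Real performance: Pearson correlation between predicted and actual
#' response per test pair, averaged over channels. Random performance:
#' `n_null` correlations of each stimulus with a randomly drawn mismatched
#' response from the pool. The model beats chance if its mean real r
#' exceeds the 97.5th percentile of the null distribution.
#'
#' @param model An `strf_model`.
#' @param pairs A `pair_set`; its test rows are evaluated.
#' @param n_null Null draws (default 1000; < 100 is an error).
#' @param seed Integer seed.
#' @param null_pool Optional list of response matrices for the null draws
#'   (default: all pair responses, train and test, mismatched).
#' @return A `strf_performance`: list with `per_trial` tibble, `mean_r`,
#'   `null_r`, `null_q975`, `above_chance`.
#' @export
evaluate_strf <- function(model, pairs, n_null = 1000, seed = 1,
                          null_pool = NULL) {
  if (n_null < 100) abort("n_null must be >= 100")
  test <- pairs[pairs$role == "test", ]
  if (!nrow(test)) abort("no test pairs")
  preds <- lapply(test$features, function(f) predict(model, f))
  real <- vapply(seq_len(nrow(test)), function(i) {
    mean_channel_cor(preds[[i]], test$response[[i]])
  }, numeric(1))
  pool <- null_pool %||% pairs$response
  test_rows <- which(pairs$role == "test")
  set.seed(substream_seed(seed, "strf_null"))
  null_r <- vapply(seq_len(n_null), function(k) {
    i <- sample.int(nrow(test), 1)
    j <- sample.int(length(pool), 1)
    if (is.null(null_pool) && length(pool) > 1 && j == test_rows[i]) {
      j <- (j %% length(pool)) + 1 # force a mismatched pairing
    }
    n <- min(ncol(pool[[j]]), ncol(preds[[i]]))
    mean_channel_cor(preds[[i]][, seq_len(n), drop = FALSE],
                     pool[[j]][, seq_len(n), drop = FALSE])
  }, numeric(1))
  q <- quantile(null_r, 0.975, names = FALSE)
  structure(
    list(
      per_trial = tibble::tibble(pair_id = test$pair_id, r = real),
      mean_r = mean(real), null_r = null_r, null_q975 = q,
      above_chance = mean(real) > q
    ),
    class = "strf_performance"
  )
}

mean_channel_cor <- function(pred, actual) {
  mean(vapply(seq_len(nrow(pred)), function(ch) {
    suppressWarnings(r <- cor(pred[ch, ], actual[ch, ]))
    if (is.na(r)) 0 else r
  }, numeric(1)))
}

#' @export
print.strf_performance <- function(x, ...) {
  cat(sprintf(
    "<strf_performance: mean r = %.3f, null 97.5%% = %.3f, above chance: %s>\n",
    x$mean_r, x$null_q975, x$above_chance
  ))
  invisible(x)
}

#' @export
glance.strf_performance <- function(x, ...) {
  tibble::tibble(mean_r = x$mean_r, null_q975 = x$null_q975,
                 null_mean = mean(x$null_r), above_chance = x$above_chance)
}

#' Decompose an STRF into temporal and spectral response functions
#'
#' TRF: kernel averaged over the bands whose centres lie in `trf_band`
#' (default 0.1-0.8 kHz) and over channels. SRF: kernel averaged over lags
#' in `srf_lags` (default 0-400 ms) and channels. Peak latency is the
#' argmax of |TRF| inside each search window; peak magnitude is the mean
#' TRF over +/- 5 ms around the latency. SRF band means summarise bands
#' below 0.1 kHz, 0.1-0.8 kHz and above 0.8 kHz.
#'
#' @param model An `strf_model`.
#' @param band_centers Band centre frequencies in Hz (length = kernel
#'   bands); default log-spaced 50-8000 Hz.
#' @param trf_band TRF averaging band in Hz (default c(100, 800)).
#' @param srf_lags SRF averaging lag window in s (default c(0, 0.4)).
#' @param peak_windows List of latency search windows in s (defaults
#'   c(0.05, 0.15) and c(0.25, 0.35)).
#' @return An `strf_decomposition`: list of tibbles `trf` (lag, weight),
#'   `srf` (band, center_hz, weight), `peaks` (window, latency, magnitude,
#'   degenerate), `srf_bands` (band_group, mean_weight).
#' @export
decompose_strf <- function(model, band_centers = NULL,
                           trf_band = c(100, 800), srf_lags = c(0, 0.4),
                           peak_windows = list(c(0.05, 0.15), c(0.25, 0.35))) {
  W <- model$weights
  d <- dim(W)
  if (is.null(band_centers)) {
    e <- exp(seq(log(50), log(8000), length.out = d[2] + 1))
    band_centers <- sqrt(e[-1] * e[-length(e)])
  }
  need <- max(srf_lags[2], vapply(peak_windows, max, numeric(1)))
  if (max(model$lags) < need - 1e-9) {
    abort("model lag window does not cover the decomposition windows")
  }
  ch_mean <- apply(W, c(2, 3), mean) # band x lag
  in_band <- band_centers >= trf_band[1] & band_centers <= trf_band[2]
  trf <- colMeans(ch_mean[in_band, , drop = FALSE])
  lag_sel <- model$lags >= srf_lags[1] & model$lags <= srf_lags[2]
  srf <- rowMeans(ch_mean[, lag_sel, drop = FALSE])
  half_ms <- round(0.005 * model$fs)
  peaks <- dplyr::bind_rows(lapply(seq_along(peak_windows), function(w) {
    win <- peak_windows[[w]]
    idx <- which(model$lags >= win[1] & model$lags <= win[2])
    seg <- trf[idx]
    degenerate <- all(seg == seg[1])
    pk <- idx[which.max(abs(seg))] # earliest on ties by which.max
    around <- max(1, pk - half_ms):min(length(trf), pk + half_ms)
    tibble::tibble(
      window = w, window_start = win[1], window_end = win[2],
      latency = model$lags[pk], magnitude = mean(trf[around]),
      degenerate = degenerate
    )
  }))
  groups <- cut(band_centers, c(-Inf, 100, 800, Inf),
                labels = c("low", "mid", "high"))
  srf_bands <- tibble::tibble(band_group = levels(groups)) |>
    dplyr::mutate(mean_weight = vapply(.data$band_group, function(g) {
      mean(srf[groups == g])
    }, numeric(1)))
  structure(
    list(
      trf = tibble::tibble(lag = model$lags, weight = trf),
      srf = tibble::tibble(band = seq_len(d[2]), center_hz = band_centers,
                           weight = srf),
      peaks = peaks, srf_bands = srf_bands
    ),
    class = "strf_decomposition"
  )
}

#' @export
print.strf_decomposition <- function(x, ...) {
  cat("<strf_decomposition>\n")
  print(x$peaks)
  invisible(x)
}

#' TRF and SRF curves of an STRF decomposition
#'
#' @param object An `strf_decomposition`.
#' @param ... Unused.
#' @export
autoplot.strf_decomposition <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$trf, curve = "TRF (lag, ms)", x = .data$lag * 1000),
    dplyr::mutate(object$srf, curve = "SRF (band centre, Hz)",
                  x = .data$center_hz)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$weight)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "kernel weight") +
    ggplot2::theme_minimal()
}
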