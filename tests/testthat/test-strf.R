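# Spectrotemporal response function: features, pair bootstrap, ridge with
# leave-one-out cross-validation, evaluation against a mismatched null,
# and TRF/SRF decomposition.

test_that("tone energy lands in the right spectrogram band", {
  fs_in <- 8000
  t <- seq(0, 0.5, by = 1 / fs_in)[-1]
  tone <- sin(2 * pi * 1000 * t)
  sf <- spectrogram_features(tone, fs_in, target_fs = 64)
  expect_equal(dim(sf$envelopes)[1], 16)
  band_energy <- rowMeans(sf$envelopes^2)
  in_band <- which(sf$band_edges[-17] <= 1000 & sf$band_edges[-1] >= 1000)
  expect_gt(sum(band_energy[in_band]) / sum(band_energy), 0.9)
  # silence: all-zero envelopes; linearity of the magnitude
  expect_true(all(spectrogram_features(numeric(400), fs_in, 64)$envelopes == 0))
  sf2 <- spectrogram_features(2 * tone, fs_in, target_fs = 64)
  expect_equal(sf2$envelopes, 2 * sf$envelopes, tolerance = 1e-8)
})

test_that("bootstrap pairs have exact lengths and disjoint stimulus splits", {
  d <- synth_strf_data(n_stim = 50)
  pairs <- build_pairs(d$feats, d$resp, n_train = 6, train_len = 10,
                       n_test = 3, test_len = 4, seed = 2)
  expect_equal(length(attr(pairs, "train_ids")), 40)
  expect_equal(length(attr(pairs, "test_ids")), 10)
  expect_length(intersect(attr(pairs, "train_ids"), attr(pairs, "test_ids")), 0)
  train <- pairs[pairs$role == "train", ]
  for (i in seq_len(nrow(train))) {
    expect_equal(ncol(train$features[[i]]), 10 * d$fs)
    expect_equal(ncol(train$response[[i]]), 10 * d$fs)
    expect_true(all(train$stimuli[[i]] %in% attr(pairs, "train_ids")))
  }
  test <- pairs[pairs$role == "test", ]
  for (i in seq_len(nrow(test))) {
    expect_equal(ncol(test$features[[i]]), 4 * d$fs)
    expect_true(all(test$stimuli[[i]] %in% attr(pairs, "test_ids")))
  }
  expect_error(build_pairs(d$feats[1:5], d$resp[1:5]), "10 unique")
})

test_that("the ridge path equals the explicit normal-equations oracle", {
  d <- synth_strf_data(noise_sd = 0.3, seed = 9)
  pairs <- build_pairs(d$feats, d$resp, n_train = 4, train_len = 3,
                       n_test = 2, test_len = 2, ramp_frac = 0, seed = 3)
  lam <- 17
  m <- fit_strf(pairs, d$fs, lag_window = c(0, (d$n_lags - 1) / d$fs),
                lambda_grid = lam)
  # oracle: z-score the features with the training stats, build the lagged
  # design explicitly, and solve the penalised normal equations
  train <- pairs[pairs$role == "train", ]
  allf <- do.call(cbind, train$features)
  mu <- rowMeans(allf); sdv <- apply(allf, 1, sd)
  X <- do.call(rbind, lapply(train$features, function(f) {
    fz <- (f - mu) / sdv
    n_band <- nrow(fz); n_time <- ncol(fz)
    Xi <- matrix(0, n_time, n_band * d$n_lags)
    for (l in seq_len(d$n_lags)) {
      for (b in seq_len(n_band)) {
        for (t in l:n_time) Xi[t, (l - 1) * n_band + b] <- fz[b, t - l + 1]
      }
    }
    Xi
  }))
  Y <- do.call(rbind, lapply(train$response, t))
  B_oracle <- oracle_ridge(X, Y, lam)
  n_band <- nrow(allf)
  for (l in seq_len(d$n_lags)) {
    expect_equal(unname(t(m$weights[, , l])),
                 unname(B_oracle[(l - 1) * n_band + seq_len(n_band), ]),
                 tolerance = 1e-8)
  }
})

test_that("a planted kernel is recovered almost exactly without noise", {
  d <- synth_strf_data(noise_sd = 0)
  pairs <- build_pairs(d$feats, d$resp, n_train = 8, train_len = 5,
                       n_test = 2, test_len = 2, ramp_frac = 0, seed = 1)
  m <- fit_strf(pairs, d$fs, lag_window = c(0, (d$n_lags - 1) / d$fs),
                lambda_grid = c(0.001, 6, 100))
  W <- sweep(m$weights, 2, m$feature_sds, "/") # undo feature scaling
  expect_gt(cor(as.vector(W), as.vector(d$K)), 0.99)
  # the selected lambda attains the best cross-validated performance
  expect_equal(m$cv$mean_r[m$cv$lambda == m$lambda], max(m$cv$mean_r))
})

test_that("heavier ridge penalties shrink the weight norm", {
  d <- synth_strf_data(noise_sd = 0.2, seed = 21)
  pairs <- build_pairs(d$feats, d$resp, n_train = 5, train_len = 3,
                       n_test = 2, test_len = 2, seed = 4)
  norms <- vapply(c(6, 1e6), function(lam) {
    m <- fit_strf(pairs, d$fs, lag_window = c(0, (d$n_lags - 1) / d$fs),
                  lambda_grid = lam)
    sqrt(sum(m$weights^2))
  }, numeric(1))
  expect_lt(norms[2], norms[1])
})

test_that("matched models beat the mismatched null; noise models do not", {
  d <- synth_strf_data(noise_sd = 0.4, seed = 2)
  pairs <- build_pairs(d$feats, d$resp, n_train = 8, train_len = 5,
                       n_test = 4, test_len = 3, seed = 6)
  m <- fit_strf(pairs, d$fs, lag_window = c(0, (d$n_lags - 1) / d$fs))
  perf <- evaluate_strf(m, pairs, n_null = 400, seed = 3)
  expect_true(perf$above_chance)
  expect_gt(perf$mean_r, perf$null_q975)
  # against a white-noise response pool the null is centred on zero
  set.seed(31)
  noise_pool <- replicate(6, matrix(rnorm(2 * 3 * d$fs), 2), simplify = FALSE)
  perf_n <- evaluate_strf(m, pairs, n_null = 400, seed = 3,
                          null_pool = noise_pool)
  expect_lt(abs(mean(perf_n$null_r)), 0.05)
  # determinism of the null
  perf2 <- evaluate_strf(m, pairs, n_null = 400, seed = 3)
  expect_identical(perf$null_q975, perf2$null_q975)
  expect_error(evaluate_strf(m, pairs, n_null = 50), "n_null")
})

test_that("the decomposition finds a planted bump's lag and band", {
  fs <- 64
  n_band <- 16; n_lags <- round(0.45 * fs) + 1
  lag_target <- round(0.1 * fs) + 1
  e <- exp(seq(log(50), log(8000), length.out = n_band + 1))
  centers <- sqrt(e[-1] * e[-(n_band + 1)])
  band_target <- which.min(abs(centers - 300))
  W <- array(0, c(1, n_band, n_lags))
  W[1, band_target, lag_target] <- 1
  m <- structure(list(weights = W, lags = (seq_len(n_lags) - 1) / fs, fs = fs),
                 class = "strf_model")
  dec <- decompose_strf(m)
  expect_equal(dec$peaks$latency[1], (lag_target - 1) / fs, tolerance = 1e-9)
  expect_equal(which.max(abs(dec$srf$weight)), band_target)
  expect_lt(dec$peaks$latency[1], dec$peaks$latency[2])
  expect_false(any(dec$peaks$degenerate[1]))
  # all-zero kernel: flat windows are flagged degenerate
  m0 <- m; m0$weights[] <- 0
  dec0 <- decompose_strf(m0)
  expect_true(all(dec0$peaks$degenerate))
  expect_true(all(dec0$trf$weight == 0))
  expect_true(all(dec0$srf$weight == 0))
})
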