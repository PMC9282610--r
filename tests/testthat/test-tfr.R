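# Morlet wavelet decomposition, ITPC, induced power and frequency tagging.

test_that("the default bank spans 1-50 Hz with matched log-spaced cycles", {
  bank <- wavelet_bank()
  expect_equal(nrow(bank), 70)
  expect_equal(range(bank$freq), c(1, 50))
  expect_equal(range(bank$cycles), c(3, 30))
  expect_true(all(diff(bank$freq) > 0))
  expect_true(all(diff(bank$cycles) > 0))
})

test_that("a unit sinusoid yields unit-magnitude coefficients at its band", {
  fs <- 128
  times <- seq(-1, 2, by = 1 / fs)[-1]
  sig <- cos(2 * pi * 10 * times)
  trials <- make_tensor(list(matrix(sig, 1)), fs = fs, epoch_window = c(-1, 2))
  bank <- wavelet_bank(9, c(4, 25))
  tf <- tfr_transform(trials, bank)
  fi <- which.min(abs(bank$freq - 10))
  interior <- tf$valid[fi, ]
  mags <- Mod(tf$coeffs[1, 1, fi, interior])
  expect_true(all(abs(mags - 1) < 0.05))
  # phase advances 2*pi per cycle: 100 ms apart at 10 Hz -> equal phase
  ph <- Arg(tf$coeffs[1, 1, fi, interior])
  k <- round(0.1 * fs)
  dphi <- (ph[-seq_len(k)] - head(ph, -k)) %% (2 * pi)
  expect_true(all(pmin(dphi, 2 * pi - dphi) < 0.1))
})

test_that("zero input produces zero coefficients", {
  trials <- make_tensor(list(matrix(0, 1, 192)), fs = 64, epoch_window = c(-1, 2))
  tf <- tfr_transform(trials, wavelet_bank(5, c(2, 20)))
  expect_true(all(Mod(tf$coeffs) < 1e-12))
  expect_error(tfr_transform(trials, wavelet_bank(5, c(2, 40))), "Nyquist")
})

test_that("ITPC equals the mean-resultant-length oracle and stays in [0,1]", {
  set.seed(8)
  n_trial <- 7; n_time <- 96
  signals <- lapply(seq_len(n_trial), function(i) matrix(rnorm(n_time), 1))
  tf <- tfr_transform(make_tensor(signals, fs = 32, epoch_window = c(-1, 2)),
                      wavelet_bank(4, c(2, 10)))
  ip <- itpc(tf)
  expect_true(all(ip$values >= 0 & ip$values <= 1, na.rm = TRUE))
  for (fi in 1:4) {
    for (ti in c(10, 50, 90)) {
      expect_equal(ip$values[1, fi, ti],
                   oracle_resultant(tf$coeffs[, 1, fi, ti]),
                   tolerance = 1e-12)
    }
  }
})

test_that("phases at exact roots of unity cancel to ITPC 0", {
  n <- 8; fs <- 32; n_time <- 96
  times <- seq(-1, 2, by = 1 / fs)[seq_len(n_time)]
  signals <- lapply(seq_len(n), function(k) {
    matrix(cos(2 * pi * 5 * times + 2 * pi * (k - 1) / n), 1)
  })
  tf <- tfr_transform(make_tensor(signals, fs = fs, epoch_window = c(-1, 2)),
                      wavelet_bank(3, c(4, 7)))
  ip <- itpc(tf)
  fi <- which.min(abs(ip$freqs - 5))
  mid <- which.min(abs(ip$times - 0.5))
  expect_lt(ip$values[1, fi, mid], 1e-6)
})

test_that("mean ITPC of uniform phases matches a Monte-Carlo expectation", {
  # implementation path: resultant of 10 unit phasors; oracle: direct MC
  set.seed(99)
  n <- 10; reps <- 10000
  oracle_draws <- replicate(reps, oracle_resultant(exp(1i * runif(n, -pi, pi))))
  impl_draws <- replicate(reps, resultant_length(runif(n, -pi, pi)))
  se <- sd(oracle_draws) / sqrt(reps) + sd(impl_draws) / sqrt(reps)
  expect_lt(abs(mean(impl_draws) - mean(oracle_draws)), 3 * se)
})

test_that("induced power recovers planted decibel changes", {
  # stationary signal: dB near 0 everywhere
  truth0 <- ground_truth(alpha = list(freq = 10, db = 0), noise_sd = 0.2,
                         seed = 13)
  tr0 <- gen_trials(truth0, 200, 1, fs = 64, epoch_window = c(-1, 1.5))
  pm0 <- induced_power(tfr_transform(tr0, wavelet_bank(5, c(6, 14), c(3, 6))))
  interior <- pm0$times > -0.6 & pm0$times < 1.1
  dev <- abs(pm0$values[1, , interior])
  expect_lt(mean(dev), 0.15)
  expect_gte(mean(dev < 0.5), 0.95)
  # amplitude x2 at one band -> +6.02 dB
  fs <- 64
  times <- seq(-1, 1.5, by = 1 / fs)[-1]
  amp <- ifelse(times >= 0, 2, 1)
  signals <- lapply(1:4, function(i) {
    matrix(amp * cos(2 * pi * 10 * times + i), 1)
  })
  pm <- induced_power(tfr_transform(
    make_tensor(signals, fs = fs, epoch_window = c(-1, 1.5)),
    wavelet_bank(3, c(9, 11))
  ))
  fi <- which.min(abs(pm$freqs - 10))
  mid <- which.min(abs(pm$times - 0.9))
  expect_equal(pm$values[1, fi, mid], 10 * log10(4), tolerance = 0.3)
  # planted -3 dB alpha suppression recovered within 0.5 dB
  truth <- ground_truth(alpha = list(freq = 10, db = -3), noise_sd = 0.1,
                        seed = 5)
  tr <- gen_trials(truth, 60, 1, fs = 64, epoch_window = c(-1, 1.5))
  pmr <- induced_power(tfr_transform(tr, wavelet_bank(5, c(6, 14))))
  fi <- which.min(abs(pmr$freqs - 10))
  sel <- pmr$times > 0.3 & pmr$times < 1.2
  expect_equal(mean(pmr$values[1, fi, sel]), -3, tolerance = 0.5)
})

test_that("dB conversion is invertible and raw power non-negative", {
  tr <- gen_null_trials(8, 2, fs = 64, seed = 3)
  tf <- tfr_transform(tr, wavelet_bank(4, c(3, 12)))
  pm <- induced_power(tf)
  expect_true(all(pm$raw >= 0))
  bidx <- which(pm$times >= -0.8 & pm$times <= -0.2)
  base <- apply(pm$raw[, , bidx, drop = FALSE], c(1, 2), mean)
  recon <- base[1, 2] * 10^(pm$values[1, 2, 17] / 10)
  expect_equal(recon, pm$raw[1, 2, 17], tolerance = 1e-10)
})

test_that("frequency tagging detects a planted 4 Hz rhythm and not noise", {
  fs <- 64
  times <- seq(-1, 1, by = 1 / fs)[-1]
  drive <- ifelse(times >= 0, 1 + cos(2 * pi * 4 * times), 0)
  set.seed(17)
  signals <- lapply(1:30, function(i) matrix(drive + rnorm(length(times), sd = 0.5), 1))
  trials <- make_tensor(signals, fs = fs, epoch_window = c(-1, 1))
  ft <- frequency_tagging(trials, concat_len = 15, n_trials_out = 20, seed = 2)
  expect_equal(ft$spectrum$freq[2] - ft$spectrum$freq[1], 1 / 15)
  row4 <- ft$tests[ft$tests$tag == 4, ]
  expect_equal(row4$bin_freq, 4)
  expect_lt(row4$p.value, 0.001)
  expect_gt(row4$t, 0)
  # white noise: the 4 Hz peak test should usually be non-significant
  hits <- vapply(1:20, function(r) {
    tr <- gen_null_trials(225, 1, fs = fs, seed = 100 + r, epoch_window = c(-1, 1))
    tg <- frequency_tagging(tr, concat_len = 15, n_trials_out = 15, seed = r)
    any(tg$tests$p.value < 0.01 & tg$tests$t > 0)
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
  expect_error(frequency_tagging(trials, concat_len = 7.5), "whole number")
})
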