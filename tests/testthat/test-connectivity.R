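# Phase and power connectivity, statistical thresholding and degree maps.

make_tfr <- function(coeffs, fs = 32, t0 = -1) {
  d <- dim(coeffs)
  structure(
    list(coeffs = coeffs, freqs = seq_len(d[3]) + 2,
         times = t0 + (seq_len(d[4]) - 1) / fs, fs = fs,
         valid = matrix(TRUE, d[3], d[4]), onset_index = round(-t0 * fs) + 1),
    class = "tfr_tensor"
  )
}

test_that("a fixed phase delay between channels gives ISPC of 1", {
  fs <- 64
  times <- seq(-1, 1, by = 1 / fs)[-1]
  signals <- lapply(1:6, function(i) {
    ph <- runif(1, -pi, pi)
    rbind(cos(2 * pi * 6 * times + ph),
          cos(2 * pi * 6 * times + ph + 1.1))
  })
  set.seed(2)
  tf <- tfr_transform(make_tensor(signals, fs = fs, epoch_window = c(-1, 1)),
                      wavelet_bank(3, c(5, 7)))
  st <- ispc(tf)
  fi <- which.min(abs(st$freqs - 6))
  mid <- which.min(abs(st$times - 0.2))
  expect_equal(st$values[1, 2, fi, mid], 1, tolerance = 1e-6)
  # symmetry everywhere
  expect_equal(st$values[1, 2, , ], st$values[2, 1, , ], tolerance = 1e-12)
})

test_that("ISPC equals the resultant-length oracle on random coefficients", {
  set.seed(4)
  co <- array(complex(real = rnorm(10 * 3 * 2 * 5), imaginary = rnorm(10 * 3 * 2 * 5)),
              c(10, 3, 2, 5))
  st <- ispc(make_tfr(co))
  for (fi in 1:2) {
    for (ti in 1:5) {
      csd <- co[, 1, fi, ti] * Conj(co[, 3, fi, ti])
      expect_equal(st$values[1, 3, fi, ti], oracle_resultant(csd),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(st$values >= 0 & st$values <= 1, na.rm = TRUE))
})

test_that("mean null ISPC matches the Monte-Carlo resultant expectation", {
  set.seed(6)
  n_trials <- 10; reps <- 2000
  co <- array(exp(1i * runif(n_trials * 2 * 1 * reps, -pi, pi)),
              c(n_trials, 2, 1, reps)) # independent phases; bins as replicates
  st <- ispc(make_tfr(co))
  impl_mean <- mean(st$values[1, 2, 1, ])
  mc <- replicate(5000, oracle_resultant(exp(1i * runif(n_trials, -pi, pi))))
  se <- sd(mc) / sqrt(5000) + sd(st$values[1, 2, 1, ]) / sqrt(reps)
  expect_lt(abs(impl_mean - mean(mc)), 3 * se)
})

test_that("power connectivity reproduces exact and oracle rank correlations", {
  # identical power vectors -> rho 1; reversed ranks -> rho -1
  p <- array(0, c(5, 3, 1, 1))
  p[, 1, 1, 1] <- c(3, 1, 4, 1, 5)
  p[, 2, 1, 1] <- c(3, 1, 4, 1, 5)
  p[, 3, 1, 1] <- c(2, 7, 1, 8, 2)
  st <- power_connectivity(p)
  expect_equal(st$values[1, 2, 1, 1], 1)
  expect_equal(st$values[1, 3, 1, 1], oracle_spearman(c(3, 1, 4, 1, 5),
                                                      c(2, 7, 1, 8, 2)),
               tolerance = 1e-12)
  rev_ranks <- array(0, c(4, 2, 1, 1))
  rev_ranks[, 1, 1, 1] <- 1:4
  rev_ranks[, 2, 1, 1] <- 4:1
  expect_equal(power_connectivity(rev_ranks)$values[1, 2, 1, 1], -1)
  # constant power across trials is undefined -> missing
  cst <- array(1, c(4, 2, 1, 1))
  cst[, 2, 1, 1] <- rnorm(4)
  expect_true(is.na(power_connectivity(cst)$values[1, 2, 1, 1]))
  expect_error(power_connectivity(array(0, c(2, 2, 1, 1))), "3 trials")
})

test_that("random power connectivity matches the brute-force oracle", {
  set.seed(11)
  p <- array(abs(rnorm(8 * 4 * 2 * 3)), c(8, 4, 2, 3))
  st <- power_connectivity(p)
  for (fi in 1:2) {
    expect_equal(st$values[2, 4, fi, 3],
                 oracle_spearman(p[, 2, fi, 3], p[, 4, fi, 3]),
                 tolerance = 1e-12)
  }
})

toy_stack <- function(vals4, freqs = 3, times = 0) {
  # one bin, 4 channels: vals4 is the 6-vector of upper-triangle values
  m <- matrix(NA_real_, 4, 4)
  m[upper.tri(m)] <- vals4
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  structure(list(values = array(m, c(4, 4, 1, 1)), kind = "phase",
                 freqs = freqs, times = times),
            class = "connectivity_stack")
}

test_that("threshold and counts match a hand-enumerated toy case", {
  a <- toy_stack(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  b <- toy_stack(c(0.7, 0.8, 0.9, 1.0, 1.1, 1.2))
  dm <- threshold_degree(a, b, baseline_window = NULL)
  pool <- seq(0.1, 1.2, by = 0.1)
  thr <- median(pool) + 0.5 * sd(pool)
  expect_equal(dm$threshold[1, 1], thr)
  expect_equal(dm$count$a[1, 1], sum(seq(0.1, 0.6, 0.1) > thr))
  expect_equal(dm$count$b[1, 1], sum(seq(0.7, 1.2, 0.1) > thr))
  # degree conservation: global count = upper-triangle sum of the binary map
  expect_equal(dm$count$b[1, 1],
               sum(dm$binary$b[, , 1, 1][upper.tri(matrix(0, 4, 4))]))
  expect_lte(dm$count$b[1, 1], 4 * 3 / 2)
  # per-channel counts sum to twice the global count
  expect_equal(sum(dm$channel_count$b[, 1, 1]), 2 * dm$count$b[1, 1])
})

test_that("degenerate and shifted pooled distributions behave as specified", {
  a <- toy_stack(rep(0.5, 6)); b <- toy_stack(rep(0.5, 6))
  dm <- threshold_degree(a, b, baseline_window = NULL)
  expect_equal(dm$count$a[1, 1], 0) # strict inequality at the threshold
  expect_equal(dm$count$b[1, 1], 0)
  # adding a constant to all values leaves the binary maps unchanged
  set.seed(3)
  v1 <- runif(6); v2 <- runif(6)
  d1 <- threshold_degree(toy_stack(v1), toy_stack(v2), baseline_window = NULL)
  d2 <- threshold_degree(toy_stack(v1 + 5), toy_stack(v2 + 5),
                         baseline_window = NULL)
  expect_identical(d1$binary, d2$binary)
})

test_that("degree percent change is baseline-referenced", {
  set.seed(9)
  mk <- function() {
    v <- array(runif(4 * 4 * 1 * 6), c(4, 4, 1, 6))
    for (t in 1:6) {
      m <- v[, , 1, t]; m[lower.tri(m)] <- t(m)[lower.tri(m)]
      diag(m) <- NA; v[, , 1, t] <- m
    }
    structure(list(values = v, kind = "phase", freqs = 3,
                   times = seq(-0.9, 0.35, by = 0.25)),
              class = "connectivity_stack")
  }
  dm <- threshold_degree(mk(), mk(), baseline_window = c(-0.9, -0.2))
  bsel <- which(dm$times >= -0.9 & dm$times <= -0.2)
  base <- mean(dm$count$a[1, bsel])
  expect_equal(dm$percent_change$a[1, 6],
               100 * (dm$count$a[1, 6] - base) / base)
})

test_that("seed profiles average the seed rows of the binary matrix", {
  ones <- matrix(1, 5, 5)
  prof <- seed_connectivity(ones, seeds = c(1, 3))
  expect_true(all(prof$profile == 1))
  isolated <- matrix(0, 5, 5)
  expect_true(all(seed_connectivity(isolated, seeds = 2)$profile == 0))
  set.seed(5)
  m <- matrix(rbinom(25, 1, 0.5), 5, 5)
  prof <- seed_connectivity(m, seeds = c(2, 4))
  expect_equal(prof$profile, colMeans(m[c(2, 4), ]))
  expect_error(seed_connectivity(m, seeds = integer()), "empty")
  expect_error(seed_connectivity(m, seeds = 9), "invalid")
})

test_that("top-channel selection respects hemisphere grouping", {
  metric <- c(5, 1, 3, 2, 8, 4)
  hemi <- c("left", "left", "left", "right", "right", "right")
  sel <- select_top_channels(metric, k = 2, hemisphere = hemi)
  expect_setequal(sel$channel[sel$hemisphere == "left"], c(1, 3))
  expect_setequal(sel$channel[sel$hemisphere == "right"], c(5, 6))
  sel_min <- select_top_channels(metric, k = 1, hemisphere = hemi,
                                 decreasing = FALSE)
  expect_setequal(sel_min$channel, c(2, 4))
})

test_that("planted group connectivity yields higher ISPC within than between", {
  truth <- ground_truth(conn = list(freq = 5, groups = list(1:3, 4:6)),
                        noise_sd = 0.7, seed = 31)
  tr <- gen_trials(truth, 40, 6, fs = 64, epoch_window = c(-1, 1.5))
  st <- ispc(tfr_transform(tr, wavelet_bank(3, c(4, 6))))
  fi <- which.min(abs(st$freqs - 5))
  sel <- st$times > 0.3 & st$times < 1.2
  within <- c(st$values[1, 2, fi, sel], st$values[2, 3, fi, sel],
              st$values[4, 5, fi, sel], st$values[5, 6, fi, sel])
  between <- c(st$values[1, 4, fi, sel], st$values[2, 5, fi, sel],
               st$values[3, 6, fi, sel])
  expect_gt(mean(within), mean(between) + 0.2)
})
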