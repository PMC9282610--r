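# Independent brute-force oracles, written without reference to the
# package's implementation paths.

# mean resultant length of complex phasors, directly
oracle_resultant <- function(z) {
  zu <- z / sqrt(Re(z)^2 + Im(z)^2)
  n <- length(zu)
  sqrt(Re(sum(zu))^2 + Im(sum(zu))^2) / n
}

# Spearman rank correlation with average ranks for ties, from scratch
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# causal moving average by explicit summation with zero padding
oracle_moving_average <- function(x, width) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (s in (t - width + 1):t) if (s >= 1) acc <- acc + x[s]
    out[t] <- acc / width
  }
  out
}

# ridge regression by explicit normal equations on a given design
oracle_ridge <- function(X, Y, lambda) {
  XtX <- t(X) %*% X
  solve(XtX + lambda * diag(ncol(X)), t(X) %*% Y)
}

# connected components by repeated neighbourhood expansion over an
# explicit adjacency matrix (rows/cols = member bins)
oracle_components <- function(members, adj) {
  comps <- list()
  remaining <- members
  while (length(remaining)) {
    comp <- remaining[1]
    repeat {
      grown <- unique(c(comp, remaining[vapply(remaining, function(m) {
        any(adj[m, comp] | adj[comp, m])
      }, logical(1))]))
      if (length(grown) == length(comp)) break
      comp <- grown
    }
    comps[[length(comps) + 1]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

# small deterministic trial tensor built from explicit signals
make_tensor <- function(signals, fs = 64, epoch_window = c(-1, 1)) {
  # signals: list of trials, each channel x time
  n_trial <- length(signals)
  n_ch <- nrow(signals[[1]])
  n_time <- ncol(signals[[1]])
  data <- array(0, c(n_trial, n_ch, n_time))
  for (tr in seq_len(n_trial)) data[tr, , ] <- signals[[tr]]
  trial_tensor(data, fs, epoch_window)
}

# shared STRF fixture: planted kernel, features and responses
synth_strf_data <- function(n_stim = 15, fs = 64, n_band = 4, n_lags = 9,
                            noise_sd = 0, seed = 5) {
  set.seed(seed)
  K <- array(0, c(2, n_band, n_lags))
  K[1, 2, 4] <- 1; K[2, 3, 6] <- -0.5; K[1, 1, 1] <- 0.3
  feats <- lapply(seq_len(n_stim), function(i) {
    f <- matrix(abs(rnorm(n_band * fs)), n_band)
    # silent tail: responses are generated per stimulus with zero history,
    # so concatenated designs must not leak features across stimulus seams
    f[, (ncol(f) - n_lags + 1):ncol(f)] <- 0
    f
  })
  resp <- lapply(feats, function(f) {
    oscbind:::kernel_predict(K, f, ncol(f)) +
      matrix(rnorm(2 * ncol(f), sd = noise_sd), 2)
  })
  list(K = K, feats = feats, resp = resp, fs = fs, n_lags = n_lags)
}

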