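# Contrast metrics for the binding simulation (phrase vs sentence):
# frequency-combined PO power, PO-S power coupling, PO phase coherence and
# PO-S phase coupling, each with a paired t test across drive pairs (or
# randomizations, for phase coherence).

#' Contrast metrics between phrase and sentence propagations
#'
#' Computes, from the node activations of both conditions driven by the same
#' drive set:
#' * `power` — per pair, DFT power of the PO-unit activations summed over
#'   PO units and over frequencies below `freq_cut` (DC excluded). More
#'   active units and broader activation mean more power; this is the
#'   model's central prediction.
#' * `power_coupling` — per pair, Spearman rank correlation between the
#'   band-limited power time-courses of each PO unit and its S-unit
#'   children, averaged over bands (log-spaced below 50 Hz) and unit pairs.
#' * `phase_coherence` — 100 randomizations per condition; each draws 30
#'   drive pairs, unit-normalises the frequency-domain representation of
#'   every PO-unit activation (phase preserved, unit length per frequency
#'   bin), and records the resultant length across the 30 drawn signals,
#'   averaged over frequency bins below `freq_cut` and over PO units. The
#'   frequency-resolved form matters: a two-child PO integrates over 250 ms,
#'   which suppresses its harmonic phase locking above ~2 Hz, so coherence
#'   grows with the number of sharply bound units.
#' * `phase_coupling` — per pair, resultant length of the cross-spectral
#'   phase series between each PO unit and its S children, averaged over
#'   unit pairs.
#'
#' Each metric is compared sentence vs phrase with a paired t test.
#'
#' @param phrase_acts,sentence_acts Node activation sets from both
#'   conditions propagated from the same drive (internally produced by
#'   [run_binding_sim()]).
#' @param templates List with the `phrase` and `sentence` templates used.
#' @param seed Integer seed for the coherence randomizations.
#' @param metrics Character subset of the four metric names to compute.
#' @param n_rand,n_draw Randomization count and signals per draw for phase
#'   coherence (defaults 100 and 30); when fewer pairs than `n_draw` are
#'   available, half of them are drawn so the subsampling stays random.
#' @param freq_cut Upper frequency bound in Hz for the combined power
#'   (default 13.5).
#' @param coupling_freqs Band centres (Hz) for the power-coupling
#'   time-courses; default 8 log-spaced values in \[2, 45\].
#' @return A `sim_metrics` object: list of tibbles `pairwise` (per-pair
#'   metric values), `coherence` (per-randomization values) and `tests`
#'   (paired t statistics).
#' @export
sim_metrics <- function(phrase_acts, sentence_acts, templates, seed = 1,
                        metrics = c("power", "power_coupling",
                                    "phase_coherence", "phase_coupling"),
                        n_rand = 100, n_draw = 30, freq_cut = 13.5,
                        coupling_freqs = exp(seq(log(2), log(45), length.out = 8))) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  fs <- attr(phrase_acts, "fs")
  acts <- list(phrase = phrase_acts, sentence = sentence_acts)
  n_pairs <- ncol(phrase_acts[[1]])
  if (n_pairs < 2) abort("need at least 2 propagated pairs")

  po_ids <- lapply(acts, function(a) names(which(attr(a, "layers") == "PO")))
  po_children <- lapply(templates, function(tpl) {
    n <- tpl$nodes
    stats::setNames(n$children[n$layer == "PO"], n$id[n$layer == "PO"])
  })

  pairwise <- tidyr::expand_grid(
    condition = c("phrase", "sentence"), pair = seq_len(n_pairs)
  )
  coherence <- NULL

  if ("power" %in% metrics) {
    pairwise$power <- unlist(lapply(c("phrase", "sentence"), function(cond) {
      po <- po_ids[[cond]]
      vapply(seq_len(n_pairs), function(p) {
        sum(vapply(po, function(id) {
          x <- acts[[cond]][[id]][, p]
          bandpower_dft(x, fs, freq_cut)
        }, numeric(1)))
      }, numeric(1))
    }))
  }

  if ("phase_coupling" %in% metrics || "power_coupling" %in% metrics) {
    phase_cp <- power_cp <- matrix(NA_real_, n_pairs, 2,
                                   dimnames = list(NULL, c("phrase", "sentence")))
    for (cond in c("phrase", "sentence")) {
      ch_map <- po_children[[cond]]
      for (p in seq_len(n_pairs)) {
        pc_vals <- pw_vals <- numeric()
        for (po in names(ch_map)) {
          xpo <- acts[[cond]][[po]][, p]
          a_po <- analytic_signal(xpo)
          if ("power_coupling" %in% metrics) {
            po_pow <- Mod(morlet_convolve(cbind(xpo), fs, coupling_freqs,
                                          rep(6, length(coupling_freqs))))^2
          }
          for (s in ch_map[[po]]) {
            xs <- acts[[cond]][[s]][, p]
            if ("phase_coupling" %in% metrics) {
              a_s <- analytic_signal(xs)
              csd <- a_po * Conj(a_s)
              pc_vals <- c(pc_vals, resultant_length(csd))
            }
            if ("power_coupling" %in% metrics) {
              s_pow <- Mod(morlet_convolve(cbind(xs), fs, coupling_freqs,
                                           rep(6, length(coupling_freqs))))^2
              rho <- vapply(seq_along(coupling_freqs), function(fi) {
                cor(po_pow[fi, , 1], s_pow[fi, , 1], method = "spearman")
              }, numeric(1))
              pw_vals <- c(pw_vals, mean(rho))
            }
          }
        }
        if ("phase_coupling" %in% metrics) phase_cp[p, cond] <- mean(pc_vals)
        if ("power_coupling" %in% metrics) power_cp[p, cond] <- mean(pw_vals)
      }
    }
    if ("phase_coupling" %in% metrics) {
      pairwise$phase_coupling <- c(phase_cp[, "phrase"], phase_cp[, "sentence"])
    }
    if ("power_coupling" %in% metrics) {
      pairwise$power_coupling <- c(power_cp[, "phrase"], power_cp[, "sentence"])
    }
  }

  if ("phase_coherence" %in% metrics) {
    set.seed(substream_seed(seed, "coherence"))
    n_time <- nrow(phrase_acts[[1]])
    fbins <- (seq_len(n_time) - 1) * fs / n_time
    sel <- fbins > 0 & fbins < freq_cut
    if (n_draw >= n_pairs) n_draw <- max(2, ceiling(n_pairs / 2))
    # each condition gets its own independent randomization draws; the
    # paired t across randomization indices then compares two independent
    # sampling distributions of the coherence statistic
    vals <- lapply(c("phrase", "sentence"), function(cond) {
      draws <- lapply(seq_len(n_rand), function(r) sample.int(n_pairs, n_draw))
      po <- po_ids[[cond]]
      # per PO unit: unit-normalized spectral coefficients (bins x pairs)
      sp <- lapply(po, function(id) {
        f <- mvfft(acts[[cond]][[id]])[sel, , drop = FALSE]
        f / Mod(f)
      })
      vapply(seq_len(n_rand), function(r) {
        mean(vapply(sp, function(S) {
          mean(Mod(rowMeans(S[, draws[[r]], drop = FALSE])))
        }, numeric(1)))
      }, numeric(1))
    })
    coherence <- tibble::tibble(
      randomization = rep(seq_len(n_rand), 2),
      condition = rep(c("phrase", "sentence"), each = n_rand),
      coherence = c(vals[[1]], vals[[2]])
    )
  }

  tests <- sim_metric_tests(pairwise, coherence, metrics)
  structure(
    list(pairwise = pairwise, coherence = coherence, tests = tests,
         n_pairs = n_pairs),
    class = "sim_metrics"
  )
}

# power below `freq_cut` Hz, DC excluded
bandpower_dft <- function(x, fs, freq_cut) {
  n <- length(x)
  sp <- Mod(fft(x))^2 / n^2
  freqs <- (seq_len(n) - 1) * fs / n
  sum(sp[freqs > 0 & freqs < freq_cut])
}

sim_metric_tests <- function(pairwise, coherence, metrics) {
  rows <- list()
  for (m in intersect(c("power", "power_coupling", "phase_coupling"), metrics)) {
    s <- pairwise[[m]][pairwise$condition == "sentence"]
    p <- pairwise[[m]][pairwise$condition == "phrase"]
    rows[[m]] <- paired_t_row(m, s, p)
  }
  if ("phase_coherence" %in% metrics && !is.null(coherence)) {
    s <- coherence$coherence[coherence$condition == "sentence"]
    p <- coherence$coherence[coherence$condition == "phrase"]
    rows$phase_coherence <- paired_t_row("phase_coherence", s, p)
  }
  dplyr::bind_rows(rows)
}

# paired t with the degenerate zero-difference case mapped to t = 0
paired_t_row <- function(metric, s, p) {
  if (sd(s - p) == 0) {
    t <- 0; df <- length(s) - 1; pval <- 1
  } else {
    tt <- t.test(s, p, paired = TRUE)
    t <- unname(tt$statistic); df <- unname(tt$parameter); pval <- tt$p.value
  }
  tibble::tibble(metric = metric, t = t, df = df, p.value = pval,
                 mean_sentence = mean(s), mean_phrase = mean(p))
}

#' Run the full binding simulation
#'
#' Generates `n_pairs` shared drives, propagates each through the phrase and
#' sentence templates, and computes the contrast metrics.
#'
#' @inheritParams gen_drive
#' @inheritParams sim_metrics
#' @param phrase,sentence Structure templates (defaults [phrase_template()]
#'   and [sentence_template()]).
#' @return A `sim_metrics` object (see [sim_metrics()]).
#' @export
run_binding_sim <- function(n_pairs = 100, fs = 1000, duration = 12,
                            noise_sd = 0.2, seed = 1,
                            phrase = phrase_template(),
                            sentence = sentence_template(),
                            metrics = c("power", "power_coupling",
                                        "phase_coherence", "phase_coupling")) {
  drive <- gen_drive(n_pairs, fs, duration, noise_sd, seed)
  ph <- propagate_all(phrase, drive)
  se <- propagate_all(sentence, drive)
  sim_metrics(ph, se, templates = list(phrase = phrase, sentence = sentence),
              seed = seed, metrics = metrics)
}

#' @export
print.sim_metrics <- function(x, ...) {
  cat(sprintf("<sim_metrics: %d drive pairs>\n", x$n_pairs))
  print(x$tests)
  invisible(x)
}

#' Per-metric paired t statistics of a binding simulation
#'
#' @param x A `sim_metrics` object.
#' @param ... Unused.
#' @return Tibble with one row per metric: t, df, p.value and condition means.
#' @export
tidy.sim_metrics <- function(x, ...) x$tests

#' One-row summary of a binding simulation
#'
#' @param x A `sim_metrics` object.
#' @param ... Unused.
#' @export
glance.sim_metrics <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs,
    n_metrics = nrow(x$tests),
    all_sentence_higher = all(x$tests$mean_sentence > x$tests$mean_phrase)
  )
}

#' Plot the per-pair metric distributions of a binding simulation
#'
#' @param object A `sim_metrics` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sim_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$pairwise, -c("condition", "pair"),
    names_to = "metric", values_to = "value"
  )
  if (!is.null(object$coherence)) {
    long <- dplyr::bind_rows(long, tibble::tibble(
      condition = object$coherence$condition,
      pair = object$coherence$randomization,
      metric = "phase_coherence", value = object$coherence$coherence
    ))
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$value,
                                     fill = .data$condition)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "metric value") +
    ggplot2::theme_minimal()
}
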