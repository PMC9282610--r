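# oscbind

Oscillatory neural dynamics are a candidate medium for encoding hierarchical
linguistic structure: if constituents are bound into phrases and sentences by
the *relative timing* of distributed neural ensembles (time-based binding),
then a stimulus with more constituents should produce more power, more
connectivity and more phase synchronization — even when the acoustic input is
physically indistinguishable. `oscbind` implements both halves of that
research programme as a tested R package:

1. **A time-based binding simulator.** Four syllable-rate input units (S)
   drive a layered network of propositional-object (PO), role-binding (RB)
   and proposition (P) nodes. Each non-S node integrates the sum of its
   children through a causal boxcar — 30 ms when it binds one child, 250 ms
   when it binds two — then refines the result with a zero-phase FIR low-pass
   (PO 50 Hz, RB 35 Hz, P 20 Hz) and peak-normalises. A phrase template
   (3 PO units, one binding two syllables) and a sentence template (4 PO
   units, an extra embedded proposition) are propagated from the *same*
   jittered syllable drives (one 140–230 ms burst per 250-ms slot per
   second, white noise, peak normalisation), and four contrasts are tested
   with paired t statistics across 100 drive pairs: frequency-combined
   (< 13.5 Hz) PO power, PO–S power coupling (Spearman), PO spectral phase
   coherence (100 randomizations of 30 drawn signals), and PO–S
   cross-spectral phase coupling.

2. **A neural-signal analysis suite**, validated on synthetic multichannel
   trials with planted ground truth:
   * Morlet wavelet time–frequency decomposition (1–50 Hz, 70 log-spaced
     frequencies, 3–30 cycles), intertrial phase coherence
     ITPC = |mean over trials of c/|c||, induced power in dB relative to the
     −800…−200 ms baseline, and frequency tagging of concatenated responses;
   * all-to-all connectivity: intersite phase clustering (unit-normalised
     cross-spectral density averaged over trials) and Spearman power
     connectivity, thresholded per time–frequency bin at the pooled
     median + 0.5 SD into binary graphs, degree maps and baseline
     percent change;
   * phase–amplitude coupling PAC = |mean(amp · e^{i·phase})| over an
     11 × 12 phase/amplitude grid with a circular-shift permutation z-score
     (PAC-Z) and the Bonferroni z threshold (3.73 at α = 0.05 / 528);
   * spectrotemporal response functions: 16 log-spaced band envelopes,
     bootstrap 10-s training pairs, ridge regression with leave-one-pair-out
     cross-validation over λ ∈ {6…100}, matched-vs-mismatched performance,
     and TRF/SRF decomposition with peak magnitude/latency statistics;
   * stimulus acoustics: Hilbert envelopes at 400 Hz, exact −16 dB RMS
     normalisation, per-time-bin cosine similarity with a max-statistic
     permutation threshold, representational similarity matrices, and a
     robust Bayesian (t-likelihood, ν = 30, gamma priors) spectrum
     comparison with a ±0.1 region of practical equivalence;
   * nonparametric cluster-based permutation tests over
     channel × frequency × time grids with spatial and spectrotemporal
     adjacency and a max-cluster-mass null.

All user-facing functions take plain data or light S3 containers and return
tibbles; fitted objects have `tidy()`/`glance()` methods and `autoplot()`
figures.

## Worked example

Run a reduced binding simulation (20 drive pairs instead of 100) and test
the four phrase/sentence contrasts:

```r
library(oscbind)
sim <- run_binding_sim(n_pairs = 20, seed = 42)
tidy(sim)
#> # A tibble: 4 × 6
#>   metric              t    df  p.value mean_sentence mean_phrase
#>   <chr>           <dbl> <dbl>    <dbl>         <dbl>       <dbl>
#> 1 power           63.0     19 1.59e-23         0.233       0.173
#> 2 power_coupling  97.8     19 3.84e-27         0.912       0.541
#> 3 phase_coupling  78.7     19 2.35e-25         0.559       0.471
#> 4 phase_coherence  6.00    99 3.23e- 8         0.330       0.320
```

Every metric is higher for the sentence structure: the extra PO unit and the
sharper (30 ms) binding windows add combined low-frequency power, and the
harmonic phase locking destroyed by the phrase's 250-ms two-child
integration raises the sentence's spectral phase coherence. `autoplot(sim)`
draws the per-pair distributions.

Planted effects are recovered by the analysis stages, e.g. theta-phase /
low-gamma-amplitude coupling:

```r
truth  <- ground_truth(pac = list(phase_freq = 4, amp_freq = 32, depth = 1),
                       noise_sd = 0.15, seed = 8)
trials <- gen_trials(truth, n_trials = 8, n_channels = 1, fs = 128,
                     epoch_window = c(-1, 1.6))
res <- pac_grid(trials, channels = 1, n_perm = 300, seed = 4)
res[which.max(res$z), ]
#>   channel phase_freq amp_freq    pac     z
#> 1       1        5.5     35.8  0.359   4.6
bonferroni_z(0.05, 11 * 12 * 4)
#> [1] 3.732051
```

The maximal PAC-Z lands one grid step from the planted (4 Hz, 32 Hz) cell
and exceeds the Bonferroni threshold of 3.73.

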