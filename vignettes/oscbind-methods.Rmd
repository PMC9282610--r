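---
title: "oscbind: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{oscbind: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the time-based binding simulation, the oscillatory analysis suite, the
synthetic-data generator that validates it, and the numerical decisions
taken where the design was genuinely open.

## The time-based binding model

The simulator expresses the hypothesis that hierarchical linguistic
structure is encoded by the *relative timing* of distributed ensembles.
Four syllable input units (S) fire once per second, each inside its own
250-ms slot, as a rectangular burst of random duration uniform in
140–230 ms (the non-isochronous 4–7 Hz syllable range) with a random
onset that keeps the burst inside its slot. White Gaussian noise
(SD 0.2 relative to the unit burst) is added and each sequence is
normalised by pointwise division by its maximum.

Every non-S node performs three steps, in topological order:

1. **Time-based binding.** The node's activation is a *causal* moving
   average of the sum of its children's activations: a value at time *t*
   averages only the input in the preceding window, with the pre-signal
   region treated as zero. The window is 30 ms for a one-child node and
   250 ms for a two-child node — binding two constituents requires
   integrating across their staggered firing. A step input therefore
   produces a linear ramp of the window's length and then a plateau.
   (Scaling the boxcar by its length instead of its reciprocal only
   rescales the signal and is removed by the final normalisation; the
   moving-average form is used.)
2. **Refinement.** A zero-phase FIR low-pass (windowed sinc designed by
   `signal::fir1`, order 3·fs/cutoff forced even, applied
   forward–backward via `filtfilt`) with layer-specific cutoffs:
   PO 50 Hz, RB 35 Hz, P 20 Hz, expressing increasing integration up the
   hierarchy.
3. **Amplitude normalisation.** Pointwise division by the maximum, so
   activations are comparable across layers; all-zero signals skip the
   division (a zero drive propagates as exact zeros).

The phrase template has three PO units (the two middle syllables bind
into one PO through a 250-ms window), two RBs and one proposition; the
sentence template has four one-child POs, two RBs, and an embedded
determiner-phrase proposition under a top-level sentence proposition —
one more non-S node and the same drive. The exact wiring is a modelling
choice (only the layer counts are constrained by the theory); both
templates ship as YAML files under `inst/extdata/` and can be swapped
without code changes.

### Contrast metrics

All metrics compare sentence vs phrase with paired t tests across
100 drive pairs (or randomizations):

* **Power** — per pair, the DFT power of each PO activation summed over
  frequencies in (0, 13.5) Hz (DC excluded) and *summed over PO units*.
  Summation over units is deliberate: the model's central prediction is
  that more active units mean more power, and the sentence has four PO
  units against the phrase's three. Because both conditions share the
  drive, this difference is nearly deterministic and the t statistic is
  large and stable in every seed.
* **Power coupling** — per pair, the Spearman rank correlation between
  band-limited power time-courses (Morlet magnitude squared at eight
  log-spaced centre frequencies in 2–45 Hz, 6 cycles) of each PO unit
  and its S children, averaged over bands and unit pairs.
* **Phase coherence** — 100 randomizations per condition. Each draws 30
  drive pairs, unit-normalises every PO activation's DFT coefficients
  (phase preserved, unit length per frequency bin), and averages the
  resultant length across the drawn signals over all bins below
  13.5 Hz and over PO units. The frequency-resolved form is essential:
  a 250-ms boxcar has spectral nulls at 4, 8 and 12 Hz and strong sinc
  attenuation above ~2 Hz, so the phrase's two-child PO loses harmonic
  phase locking and the condition with more sharply bound units is more
  coherent. Randomization draws are independent between conditions;
  the paired t across randomization indices then compares two
  independent sampling distributions of the statistic.
* **Phase coupling** — per pair, the resultant length of the
  cross-spectral phase series (analytic signal of the PO times the
  conjugate analytic signal of each S child), averaged over unit pairs.

Defaults: 100 pairs, 12-s drives, 1000 Hz sampling (configurable; the
rate is a simulation choice, not a property of the model), noise
SD 0.2. The paired t for power under these conditions is far larger
than the phase-coherence t: with a shared drive the unit-count effect
has almost no cross-pair variance, while coherence inherits the
randomization sampling noise.

## The synthetic-data generator

`gen_trials()` plants parameterised effects in trial × channel × time
tensors so each analysis stage has a known answer:

* **Phase locking** — a stimulus-locked post-onset oscillation whose
  trial phase is 0 with probability `strength` and uniform otherwise,
  so the expected intertrial resultant equals `strength` exactly
  (and is exactly 1 at strength 1 with zero noise).
* **Alpha power change** — an oscillation whose post-onset amplitude is
  scaled by `10^(db/20)`, so induced power changes by `db` decibels.
* **Phase–amplitude coupling** — a carrier at the amplitude frequency
  modulated by `1 + depth·cos(phase)` of a slow oscillation with random
  per-trial phase.
* **Connectivity** — channel groups sharing one random per-trial phase
  (high within-group, low between-group phase-lag consistency).
* **Encoding kernels** — a channel × band × lag array convolved with
  16-band envelope features.
* Additive white Gaussian noise, with an optional 1/f component
  (disabled by default; the analyses assume broadband background).

`gen_envelopes()` builds paired phrase/sentence stimulus envelopes at
400 Hz: Hann-windowed bursts of 140–230 ms at the syllable rate,
RMS-normalised to −16 dB full scale. Burst onsets, durations and
amplitude factors (SD 0.35, emulating natural stress variation) are
shared within a pair; a small per-member jitter (SD 0.05) keeps paired
envelopes similar but not identical. Without cross-item amplitude
variation the per-time-bin item vectors are nearly constant and cosine
similarity carries no information; without pair sharing the matched
similarity collapses to the null level. What the generator does *not*
emulate: recording artifacts (blinks, line noise), volume conduction,
1/f-shaped EEG spectra (unless enabled), or genuine speech acoustics —
passing tests demonstrate estimator correctness and calibration, not
performance on real recordings.

Determinism: every generator derives all randomness from an integer
seed through fixed substreams, so identical seeds give identical
tensors.

## Analysis-suite parameters and numerics

* **Wavelet bank** — 70 log-spaced frequencies in 1–50 Hz with 3–30
  cycles matched index-wise. Wavelets are scaled so a unit-amplitude
  sinusoid at a centre frequency yields coefficient magnitude 1
  anywhere in the bank. Convolution is FFT-based; samples within 3 SD
  of each frequency's wavelet are flagged in a validity mask rather
  than dropped. Small banks used in tests shrink the cycle range too —
  30 cycles at a test bank's top frequency would invalidate most of a
  short epoch.
* **ITPC / ISPC** — zero-magnitude coefficients (and cross-spectral
  densities) are treated as missing, not as phase zero. Both equal a
  direct mean-resultant-length computation to 1e-12.
* **Induced power** — `10·log10(power/baseline)` per channel and
  frequency with the −800…−200 ms baseline; a zero baseline is an
  error, not an infinity.
* **Degree maps** — per time–frequency bin, threshold = pooled
  (both conditions, upper triangle) median + 0.5 SD; binarisation is
  strictly greater-than, so an all-equal bin has zero degree; adding a
  constant to all values leaves the binary graphs unchanged. Percent
  change uses the baseline mean; bins with zero baseline are missing.
  Both global and per-channel counts are exported (the two natural
  readings of "degree").
* **Frequency tagging** — concatenations partition the trial pool
  disjointly whenever it is large enough; re-using identical 1-s
  epochs adds a shared component exactly at the integer-Hz tag bins
  and breaks the exchangeability the across-concatenation t test
  needs. Each concatenation is referenced to its own baseline-stage
  spectrum for the same reason.
* **PAC** — `pac_raw` is the magnitude of the amplitude-weighted mean
  phasor; `pac_z` shifts the amplitude series circularly (offsets
  uniform on [1, N−1]; the amplitude multiset is preserved exactly).
  The grid version computes PAC per trial, averages, and shifts each
  trial independently in the null — shifting one concatenated series
  would let rhythmic couplings re-align under the null and deflate z
  at truly coupled cells. The analysis window is −50…1500 ms; the
  one-tailed Bonferroni threshold at α = 0.05 over 11 × 12 × 4 tests
  is z = 3.73.
* **STRF** — lags default to 0–500 ms (covering the 0–400 ms region of
  interest); features are z-scored per band on training statistics and
  the same transform is applied at test. Ridge solves the penalised
  normal equations via Cholesky on accumulated cross-products, with
  leave-one-pair-out folds obtained by subtracting each fold's
  contribution; the selected λ always attains the best cross-validated
  mean Pearson r (averaged over channels, then folds). The
  mismatched-pair null pools *all* responses (train and test): with
  only a handful of test pairs the null percentile would otherwise be
  a two-point statistic. TRF peak latency ties break to the earliest
  sample and flat search windows are flagged degenerate; peak
  magnitude averages ±5 ms around the latency.
* **Similarity tests** — 50-ms moving-average smoothing; the
  permutation null shuffles each envelope's time bins *independently*
  and takes the maximum similarity over bins; the threshold is the
  null's 95th percentile. A single shared permutation almost always
  maps some bin near itself and drives the threshold to the matched
  value.
* **Bayesian spectrum comparison** — BEST-like two-group model per
  frequency bin: t likelihood with fixed ν = 30, gamma prior on each
  group mean (mean = pooled mean, SD = 5 × pooled SD), log-normal
  prior on group SDs, sampled by random-walk Metropolis-within-Gibbs
  (two chains, proposal steps scaled by n, split-chain R-hat
  reported). The ROPE of ±0.1 is applied to the *standardised* mean
  difference — the printed range is only meaningful on a standardised
  scale. A consequence worth stating plainly: with n = 50 items per
  group the 95% HDI of a standardised difference is ~±0.39 wide and
  can never fit inside ±0.1, so equivalence is only reachable with
  thousands of items; the tests verify the decision rule at n = 2600.
  Analysed bins are capped (default 40 from the low end) to bound run
  time; the speech-relevant envelope energy sits there.
* **Cluster permutation test** — paired design; per-bin dependent t
  with entry threshold p < 0.05 two-sided; components are formed
  separately for positive and negative t over channel-neighbour plus
  consecutive frequency/time adjacency; cluster mass is the summed t;
  the null is the maximum absolute mass under random within-subject
  sign flips (sign flips leave squared differences unchanged, so the
  whole permutation t map is computed with one matrix product).
  Cluster p values use the (count + 1)/(n_perm + 1) estimator, so the
  smallest attainable p at 1000 permutations is ~0.001. Channel
  adjacency defaults to 4 symmetrised nearest neighbours from montage
  coordinates.

## Problem sizes

The shipped test suite runs the binding simulation once at full scale
(100 pairs) and replicates the direction checks at 12–30 pairs across
seeds; null calibrations use 500 replicates (PAC-Z nulls at 1000
permutations; cluster familywise error at 200 permutations on a
10 × 2 × 5 × 12 grid; STRF false positives on 12-stimulus noise sets).
These sizes are the package's validation design: large enough for the
binomial bands asserted, small enough to run on one CPU in minutes.

## Known limitations

* The simulator's templates are one defensible wiring of the theory;
  other wirings with the same layer counts are configurable but
  untested.
* The t statistic of the power contrast is intrinsically large under a
  shared drive (the unit-count difference has almost no cross-pair
  variance); treat its magnitude as implementation-conditional, the
  direction and significance regime as the model's prediction.
* The analysis suite is sensor-space only: no source localisation, no
  volume-conduction correction, no artifact handling.
* `spectrum_rope` with default chains (10 000 post warm-up) is slow on
  many bins; the bin cap and shorter chains are the intended desk-scale
  configuration.
* Audio enters as numeric vectors; no WAV reader is bundled.
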