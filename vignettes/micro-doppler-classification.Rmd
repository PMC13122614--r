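---
title: "Classifying insect wingbeats from mmWave micro-Doppler signatures"
author: "wingbeatRadar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying insect wingbeats from mmWave micro-Doppler signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingbeatRadar)
```

# The signal model

A continuous-wave radar pointed at a flying insect receives a reflection
whose quadrature-demodulated baseband is a complex time series. We model it
as the sum of three components: broadband noise (receiver noise plus
background clutter), a slow Doppler component from gross body movement, and
a periodic micro-Doppler component from the beating wings. Because wing
motion is repetitive, the wingbeat component is a sum of `N` harmonics of
the fundamental wingbeat frequency `fw`: harmonic `n` contributes
`A_n * exp(1i*(2*pi*n*fw*t + phi_n))`. We implement the harmonic sum as a
complex exponential because the recorded waveform itself is the complex
I/Q baseband; the harmonic amplitudes `A_n` encode wing kinematics and are
species-informative beyond `fw` alone.

The synthetic generator (`synthesizeRecording()`, `generateCohort()`)
realizes exactly this decomposition, so every downstream stage can be
exercised and tested without access to real captures:

* **Noise** is circularly symmetric complex white Gaussian; its power is set
  by `snrDb`, the wingbeat-to-noise power ratio relative to `sum(A_n^2)`.
  Real captures contain structured multipath clutter rather than white
  noise; the white model is a testable stand-in, and the detection
  statistic is explicitly validated against it (the Monte-Carlo null of the
  harmonic ratio).
* **Body motion** is complex white noise shaped by a 4th-order Butterworth
  low-pass at `bodyMotionBandwidth` (< 50 Hz), scaled to a target RMS. Only
  its spectral confinement below the high-pass cutoff matters downstream,
  and that property is asserted end-to-end.
* **Wingbeat** is the harmonic sum, gated by a bout schedule. Each subject
  draws its fundamental once from the species' `(fwMean, fwSd)`
  distribution (clamped at three sigma) and its harmonic envelope with
  log-normal variation (`envelopeSubjectSd`), which is what makes
  subject-grouped evaluation meaningful: segments of one individual share a
  signature.

The capture convention mirrors the measurement protocol the package
targets: 60 s at `fs = 1000` samples/s with inclusive endpoints, i.e.
60,001 samples per recording, carrier 30 GHz (metadata only).

## Default study conditions

`defaultSpeciesProfiles()` defines five synthetic species profiles with
fundamentals 120/160/200/240/300 Hz, between-subject SD 8 Hz, SNR 15 dB,
and harmonic envelopes `c(1, .6, .35)`, `c(1, .35)`, `c(1, .55)`, `c(1)`,
`c(1)`. Harmonic counts are capped by Nyquist at 1 kHz
(`N * (fwMean + 3*fwSd) < 500 Hz`), which forces the two highest-pitched
profiles to a single harmonic; separation between those two rests on the
fundamental and its band placement. These numbers are choices for
testability — well separated at the population level, overlapping nowhere
at three sigma — not calibrations to any real dataset. Cohorts schedule
about five flight bouts per 60 s recording with log-uniform lengths
between 0.3 and 8 s, so that multi-duration scanning finds material at
every window length.

# Preprocessing

Each recording is normalized per-recording (complex mean removed, unit RMS
magnitude) so that detection thresholds are comparable across its frames,
then high-pass filtered with a second-order Chebyshev type-I filter, 50 Hz
cutoff, 1 dB passband ripple, applied to the I and Q channels identically.
Filtering is forward-backward (zero phase) by default: zero-phase filtering
squares the magnitude response and preserves the relative phases of the
wingbeat harmonics, which the cepstral features consume. Ripple, order and
mode are exposed in `FilterSpec` because only family/order/cutoff are
pinned by the protocol; results are mildly sensitive to the remaining
choices. The 50 Hz cutoff reflects hymenopteran wingbeat fundamentals,
which sit above 50 Hz, while body motion sits below.

Frames are cut with a Hann taper, 2 s length and 1 s overlap by default;
frame `k` starts at `k * hop` and the frame count is
`floor((len/fs - window)/hop) + 1`.

# Detecting wing-flap segments

For a real frame `x` of length `L`, the normalized autocorrelation

```
Psi(k) = sum_n x[n] x[n+k] / sqrt(sum_n x[n]^2 * sum_n x[n+k]^2)
```

(sums over the overlapping part) compares the frame with lagged copies of
itself. The **harmonic ratio** is `max Psi(k)` over lags `[K0, K]`, clamped
to `[0, 1]`, where `K = round(0.04 * fs)` — 40 samples = 40 ms at 1 kHz,
i.e. a 25 Hz minimum fundamental — and `K0` adapts per frame to the first
zero crossing of `Psi` (`Psi(k-1)*Psi(k) <= 0`, with `Psi(0) = 1`). When
`Psi` never crosses zero the lower bound falls back to lag 1; this retains
the frame rather than discarding it, and is flagged as the
deviation-prone corner of the statistic. Frames whose harmonic ratio
exceeds a threshold (default 0.4, motivated by the observation that
stationary insects stay below 0.4) are retained as micro-Doppler segments.
The statistic is computed on the real part of the filtered signal by
default (`channel` option: real/imag/magnitude), since the formulation is
defined for real sequences.

Two scanning conventions are provided. `detectSegments()` scans one
duration with overlapping frames and retains every qualifying frame — the
convention under which per-duration segment tallies are simply counts of
qualifying frames. `resegmentDurations()` scans a descending ladder of
durations at 50% overlap; in its default *exclusive* mode each region of
signal contributes only at the longest duration for which it qualifies,
the convention of the duration-sweep experiment (no double counting of the
same signal across durations).

# The 70-feature description

`defaultFeatureRegistry()` assembles exactly 70 named features per
segment; the registry is configuration-driven and validates its count, so
an alternative feature table can be specified without touching code.

* **42 cepstral features** — 14 static MFCCs, 14 deltas, 14 delta-deltas.
  At 1 kHz the mel filterbank spans 0–500 Hz with 26 triangular bands.
  Segments are analysed in subframes of `duration/8` with 50% hop (0.25 s
  and 0.125 s for a 2 s segment), scaled proportionally for shorter
  segments so the delta features stay defined at every supported duration;
  fewer than four subframes are zero-padded up. Deltas are regression
  slopes over two neighbouring subframes each side; aggregation over
  subframes is the mean. Log energies use a relative floor
  (`max(E) * 1e-12`), which keeps the cepstrum defined for line spectra
  and — unlike an absolute floor — preserves exact amplitude-scale
  invariance of `mfcc1..mfcc13`.
* **3 fundamental estimates** — `PEF_F0` (comb filter bank scoring mean
  periodogram power at candidate harmonics; the mean rather than the sum
  penalizes subharmonics), `WT_F0` (Morlet CWT ridge, `omega0 = 6`,
  unit-peak wavelet normalization so a tone's ridge sits exactly at its
  frequency), and `NCF_F0` (autocorrelation pitch on an 8x band-limited
  upsampled segment — at 1 kHz a 300 Hz fundamental has a period of ~3
  samples, far too coarse for direct lag search — with an octave guard
  taking the smallest of near-equal peaks and parabolic refinement). All
  three search 50–400 Hz: below 50 Hz nothing survives the high-pass
  filter, above 400 Hz harmonics approach Nyquist. Estimates whose peak
  does not stand out from the candidate-score median are flagged missing;
  the thresholds (20 for PEF, 4 for CWT, peak correlation 0.3 for NCF)
  were fixed from the separation between noise-only and weakest-signal
  quality ratios. Missing PEF/WT estimates are imputed with the NCF
  estimate, a missing NCF with the 50 Hz search floor, so the vector is
  always fully finite.
* **1 harmonic ratio** — the segment's detection statistic, carried into
  the feature vector.
* **9 band-power ratios** — fractions of one-sided Hann periodogram power
  in contiguous 50-Hz bands from 50 to 500 Hz.
* **15 spectral/temporal descriptors** — periodogram moments (centroid,
  spread, skewness, excess kurtosis), flatness, normalized entropy, crest,
  85% rolloff, slope, decrease, flux across eight half-overlapping
  subframes, peak frequency, RMS energy, zero-crossing rate, and the
  time-domain crest factor.

# The hierarchical cascade

Classification follows the taxonomy: stage 1 separates the families
Vespidae and Apidae on all samples; Vespidae finalizes immediately as
*Vespula vulgaris*. Stage 2 separates the Apidae genera *Apis* and
*Bombus*; *Apis* finalizes as *Apis mellifera*. Stage 3 separates the
three *Bombus* species. Stages 1–2 are gradient-boosted tree ensembles and
stage 3 an extremely-randomized-trees ensemble, matching the rationale
that boosting captures the high-level splits with low bias while
randomized splits generalize better where classes are subtly separated.
Each stage trains on true labels of its stratum with inverse-frequency
class weights (`total/(n_classes * count_c)`, per-sample mean weight 1).
Defaults: 300 boosting rounds, depth 6, learning rate 0.1; 300 randomized
trees; all seeded, single-threaded, deterministic. Probability ties break
towards the alphabetically first class. Over- and under-sampling are not
implemented as defaults since they did not help in the setting this
pipeline reproduces.

The train/test split is grouped by subject: within each species, randomly
ordered subjects are assigned to the test side until the realized sample
fraction is closest to the 20% target (the target is a *sample* fraction
realized greedily at subject granularity — exact 80/20 is impossible under
grouping). Evaluation reports cumulative confusion matrices at family,
genus and species granularity with earlier-finalized classes carried
forward, per-class precision/recall/F1, accuracy (trace/total), and the
micro-averaged F1, which equals accuracy for single-label problems.

`durationSweep()` chains detection (exclusive across durations), feature
extraction, one shared subject split, per-duration fits and evaluations
over the duration ladder 2, 1, 0.8, 0.6, 0.4, 0.2, 0.1 s.

# Explaining decisions

`exactShapley()` enumerates all coalitions (guarded to 12 features) under
the interventional value function: a coalition's value is the mean model
output over hybrid rows taking in-coalition features from the explained
instance and the rest from background rows. `treeAttributions()` computes
the same quantity in closed form for tree ensembles: each leaf is an
axis-aligned box, so for one (leaf, background row) pair the coalition
game is an indicator game whose Shapley value has the closed form
`(r-1)! q! / (r+q)!` per required-in feature and `-r! (q-1)! / (r+q)!` per
required-out feature. The two routes agree to numerical precision, which
the tests assert; the closed form is exact, not an approximation. Boosted
stages are attributed on the log-odds margin, the probability forest on
the predicted class's probability. For cascade decisions, each sample is
attributed by the stage that finalized its label, and `rankFeatures()`
orders features by mean absolute attribution, overall or per class. The
default background is 100 seeded training rows; attributions are means
over the background, so duplicating rows changes nothing.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on synthetic
data: a cohort of 5 species x 4 subjects x one 60 s recording (the
smallest size at which subject-grouped splitting is meaningful in every
species), a 200-segment estimator-recovery cohort at SNR 20 dB, 1000-draw
Monte-Carlo nulls, and toy tree models for the attribution oracle. On
these conditions the fundamental estimators recover `fw` with median
errors well under 1 Hz at 2 s, and the cascade separates the five
profiles essentially perfectly at 2 s while degrading sharply at 0.1 s,
reproducing the qualitative duration trend. Degenerate inputs are defined
rather than erroneous: zero-variance frames have harmonic ratio 0,
zero-energy sub-windows have `Psi = 0`, silent segments yield imputed
fundamentals, and all-zero inputs pass through normalization unchanged.

# Known limitations

* The synthetic generator does not model multipath clutter, container-wall
  echoes, range-dependent SNR, or amplitude modulation of the harmonic
  envelope within a bout. Passing tests demonstrate the pipeline's
  correctness and its behaviour under the stated conditions, not
  performance on real captures.
* With 4 subjects per species the test side of a grouped split holds about
  one subject per species, so end-to-end accuracy moves in whole-subject
  steps; a test subject whose fundamental falls at the edge of its
  species' range can be misrouted wholesale. Larger cohorts smooth this
  out.
* The 50-Hz band-power bins alias fundamentals that fall in the same bin
  (e.g. 255 Hz and 290 Hz), which can dominate tree splits when
  fundamentals of different species share a bin.
* The harmonic-ratio fallback (`K0 = 1` when `Psi` has no zero crossing)
  can inflate the statistic for strongly low-pass frames; with the default
  high-pass preprocessing such frames are rare.
* Exact attribution cost grows with trees x leaves x background x
  explained rows; it is intended for moderate explanation sets (tens of
  rows, ~100 background rows), not whole datasets.
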