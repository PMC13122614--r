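# wingbeatRadar

Taxonomic classification of flying insects from continuous-wave
millimetre-wave radar reflections.

Insect wing flapping imprints a periodic micro-Doppler modulation on a
radar echo: harmonics of the wingbeat fundamental `f_w` appear as parallel
bands in the short-time spectrum of the complex baseband I/Q signal. Those
harmonic patterns carry taxonomic information that images cannot provide —
they reflect wing kinematics rather than appearance — which makes a cheap
unmodulated 30 GHz transceiver a viable, non-lethal sensor for monitoring
pollinators. This package implements the full analysis chain for such
signals, aimed at radar entomologists and ecologists prototyping
mmWave-based biodiversity monitoring:

1. **Synthesis** (`synthesizeRecording`, `generateCohort`): seeded complex
   baseband recordings following the decomposition
   `A(t) e^{j phi(t)} = s_noise(t) + s_body(t) + s_wingbeat(t)`, with
   `s_wingbeat(t) = sum_n A_n exp(j(2 pi n f_w t + phi_n))`, organized into
   flight bouts within 60 s captures of 60,001 samples at 1 kHz.
2. **Preprocessing** (`normalizeIQ`, `highpassFilter`, `frameSignal`):
   per-recording normalization, second-order Chebyshev high-pass at 50 Hz
   (zero phase), Hann frames of 2 s with 1 s overlap.
3. **Detection** (`harmonicRatio`, `detectSegments`,
   `resegmentDurations`): the harmonic ratio
   `eta_HR = max_{k in [K0, K]} Psi(k)` of the normalized autocorrelation
   `Psi(k)`, with `K = round(0.04 fs)` (a 25 Hz minimum fundamental) and
   `K0` the first zero crossing of `Psi`; frames with `eta_HR > 0.4` are
   retained as micro-Doppler segments, at window durations from 2 s down
   to 0.1 s.
4. **Features** (`extractFeatures`, `defaultFeatureRegistry`): exactly 70
   named features per segment — 14 MFCCs with deltas and delta-deltas,
   three independent `f_w` estimators (pitch-estimation filter, Morlet
   wavelet ridge, normalized-correlation pitch), the harmonic ratio, nine
   50-Hz band-power ratios, and 15 spectral/temporal descriptors —
   returned as a `SummarizedExperiment`.
5. **Cascade** (`fitCascade`, `predictCascade`, `evaluateCascade`,
   `durationSweep`): family → genus → species hierarchy (Vespidae/Apidae,
   then Apis/Bombus, then the three *Bombus* species) with boosted-tree
   and extremely-randomized-tree stages, subject-grouped 80/20 splitting,
   class weights, cumulative confusion matrices, per-class
   `F1 = 2 P R / (P + R)` and the duration-sweep experiment.
6. **Attribution** (`treeAttributions`, `exactShapley`, `rankFeatures`):
   exact interventional Shapley attributions of stage decisions, computed
   in closed form over tree leaves and validated against brute-force
   coalition enumeration.

See the vignette (`vignettes/micro-doppler-classification.Rmd`) for the
model, the parameter choices and their rationale, and known limitations.

## Worked example

A wasp-analog recording — stationary for 6 s, then flapping from 6 to
10 s — detected and featurized:

```r
library(wingbeatRadar)

profile <- defaultSpeciesProfiles()[["Vespula vulgaris"]]
scene <- sceneConfig(durationS = 12, boutSchedule = list(c(6, 10)), seed = 7)
rec <- synthesizeRecording(profile, scene, subjectId = "S01")
rec
#> RadarRecording 'S01_r1': 12001 samples @ 1000 Hz (12.0 s)
#>   subject: S01   species: Vespula vulgaris   bouts: 1

segs <- detectSegments(rec)
segmentInfo(segs)[, c("startS", "durationS", "etaHr")]
#>   startS durationS     etaHr
#> 1      5         2 0.9023175
#> 2      6         2 0.9670411
#> 3      7         2 0.9678690
#> 4      8         2 0.9641663
#> 5      9         2 0.9171145

feats <- extractFeatures(segs)
round(SummarizedExperiment::assay(feats)[
  c("NCF_F0", "PEF_F0", "WT_F0", "HarmonicRatio"), 1:3], 3)
#>                  [,1]    [,2]    [,3]
#> NCF_F0        320.771 320.549 320.551
#> PEF_F0        320.170 320.035 320.034
#> WT_F0         320.416 320.371 320.359
#> HarmonicRatio   0.902   0.967   0.968
```

No frame starting before 5 s is retained (the stationary phase keeps the
harmonic ratio below the 0.4 threshold), the retained frames tile the
6–10 s flight bout, and all three estimators recover this subject's true
fundamental of 320.35 Hz to within half a hertz. Feeding a cohort of such
recordings to `durationSweep()` trains the cascade per duration and
reports accuracy and per-species F1; `cascadeAttributions()` +
`rankFeatures()` show which features carried each decision.

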