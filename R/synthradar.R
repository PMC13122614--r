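# Synthetic complex-baseband micro-Doppler generator.
#
# The model decomposes a down-converted continuous-wave reflection into
# noise + slow body-motion Doppler + a periodic wingbeat component that is a
# sum of N harmonics of the fundamental f_w. Everything here is seeded and
# deterministic so that downstream stages can be tested without real data.

nSamplesFor <- function(fs, durationS, inclusiveEndpoints) {
  round(fs * durationS) + if (inclusiveEndpoints) 1L else 0L
}

#' Synthesize the periodic wingbeat component
#'
#' Returns the complex harmonic sum
#' \code{sum_n A_n * exp(1i*(2*pi*n*fw*t + phi_n))} sampled at \code{fs}.
#' With \code{jitterSd > 0}, the instantaneous fundamental is perturbed
#' multiplicatively once per 0.5 s frame and the phase is integrated so the
#' waveform stays continuous.
#'
#' @param spec a [WingbeatSpec-class].
#' @param fs sampling rate (samples/s).
#' @param durationS duration in seconds.
#' @param seed RNG seed (used only when \code{jitterSd > 0}).
#' @param inclusiveEndpoints include both endpoints of the time grid.
#' @return complex vector.
#' @examples
#' w <- synthesizeWingbeat(wingbeatSpec(120, c(1, 0.5, 0.25)), fs = 1000,
#'                         durationS = 2)
#' @export
synthesizeWingbeat <- function(spec, fs, durationS, seed = NULL,
                               inclusiveEndpoints = FALSE) {
  validObject(spec)
  nHarm <- length(spec@amplitudes)
  if (nHarm * spec@fw * (1 + 3 * spec@jitterSd) >= fs / 2)
    stop("aliasing: N*fw*(1+3*jitterSd) = ",
         signif(nHarm * spec@fw * (1 + 3 * spec@jitterSd), 5),
         " Hz reaches Nyquist (", fs / 2, " Hz)")
  n <- nSamplesFor(fs, durationS, inclusiveEndpoints)
  if (spec@jitterSd == 0) {
    t <- (seq_len(n) - 1) / fs
    phase <- 2 * pi * spec@fw * t
  } else {
    frameLen <- max(1L, round(0.5 * fs))
    nFrames <- ceiling(n / frameLen)
    factors <- withSeed(seed, 1 + spec@jitterSd * rnorm(nFrames))
    instFreq <- spec@fw * rep(factors, each = frameLen)[seq_len(n)]
    # integrate instantaneous frequency for a phase-continuous waveform
    phase <- 2 * pi * c(0, cumsum(instFreq[-n])) / fs
  }
  out <- complex(length.out = n)
  for (h in seq_len(nHarm)) {
    out <- out + spec@amplitudes[h] *
      exp(1i * (h * phase + spec@phases[h]))
  }
  out
}

#' Synthesize the slow body-motion Doppler component
#'
#' A complex low-pass random process standing in for the Doppler reflection
#' of gross body movement: complex white Gaussian noise filtered by a 4th
#' order Butterworth low-pass at \code{bandwidthHz}, scaled to RMS
#' \code{amp}. Its spectral support lies below the 50 Hz high-pass cutoff,
#' so preprocessing removes it.
#'
#' @param amp RMS amplitude; 0 yields an all-zero sequence.
#' @param bandwidthHz bandwidth in Hz (must be < fs/2; < 50 for realistic
#'   profiles).
#' @param fs,durationS,seed,inclusiveEndpoints as in [synthesizeWingbeat()].
#' @return complex vector.
#' @export
synthesizeBodyMotion <- function(amp, bandwidthHz, fs, durationS, seed = NULL,
                                 inclusiveEndpoints = FALSE) {
  if (bandwidthHz <= 0 || bandwidthHz >= fs / 2)
    stop("bandwidthHz must lie in (0, fs/2)")
  n <- nSamplesFor(fs, durationS, inclusiveEndpoints)
  if (amp == 0) return(complex(length.out = n))
  z <- withSeed(seed, complex(real = rnorm(n), imaginary = rnorm(n)))
  bf <- signal::butter(4, bandwidthHz / (fs / 2), type = "low")
  x <- signal::filter(bf, Re(z)) + 1i * signal::filter(bf, Im(z))
  x <- as.complex(x)
  rms <- sqrt(mean(Mod(x)^2))
  if (rms > 0) x <- x * (amp / rms)
  x
}

#' Synthesize a full labelled recording
#'
#' Assembles \code{iq = noise + body motion + wingbeat} where the wingbeat
#' component is present only inside the scheduled flight bouts. The
#' subject's fundamental is drawn once from the species' \code{(fwMean,
#' fwSd)} distribution under the scene seed, and the harmonic envelope gets
#' per-subject multiplicative log-normal variation. Noise is circularly
#' symmetric complex Gaussian with power set by \code{snrDb} relative to the
#' wingbeat power \code{sum(A_n^2)}.
#'
#' @param profile a [SpeciesProfile-class].
#' @param scene a [SceneConfig-class]; its seed drives all randomness.
#' @param subjectId subject identifier (also salts the subject-level draws).
#' @param recordingId optional recording identifier.
#' @return A [RadarRecording-class] with truth annotations.
#' @examples
#' pr <- defaultSpeciesProfiles()[[1]]
#' sc <- sceneConfig(durationS = 12, boutSchedule = list(c(6, 10)), seed = 7)
#' rec <- synthesizeRecording(pr, sc, "S01")
#' @export
synthesizeRecording <- function(profile, scene, subjectId,
                                recordingId = paste0(subjectId, "_r1")) {
  validObject(profile); validObject(scene)
  n <- nSamplesFor(scene@fs, scene@durationS, scene@inclusiveEndpoints)
  # salt the scene seed with the subject id so subjects differ deterministically
  salt <- sum(utf8ToInt(subjectId)) %% 10000L
  seeds <- deriveSeeds(scene@seed + salt, 4L)

  fwSubject <- withSeed(seeds[1], {
    fw <- rnorm(1, profile@fwMean, profile@fwSd)
    # keep the subject draw inside the valid band for this species
    clamp(fw, profile@fwMean - 3 * profile@fwSd,
          profile@fwMean + 3 * profile@fwSd)
  })
  env <- withSeed(seeds[2], profile@harmonicEnvelope *
                    exp(rnorm(length(profile@harmonicEnvelope),
                              0, profile@envelopeSubjectSd)))
  wingPower <- sum(env^2)
  noisePower <- wingPower / 10^(profile@snrDb / 10)
  noise <- withSeed(seeds[3], complex(
    real = rnorm(n, sd = sqrt(noisePower / 2)),
    imaginary = rnorm(n, sd = sqrt(noisePower / 2))))

  body <- synthesizeBodyMotion(profile@bodyMotionAmp,
                               profile@bodyMotionBandwidth,
                               scene@fs, scene@durationS, seed = seeds[4],
                               inclusiveEndpoints = scene@inclusiveEndpoints)
  iq <- noise + body

  bouts <- scene@boutSchedule
  truthFw <- numeric(0)
  if (nrow(bouts)) {
    spec <- new("WingbeatSpec", fw = fwSubject, amplitudes = env,
                phases = rep(0, length(env)), jitterSd = 0)
    # one continuous harmonic waveform, gated by the bout schedule, so the
    # component is phase-coherent across bouts of one recording
    wing <- synthesizeWingbeat(spec, scene@fs, scene@durationS,
                               inclusiveEndpoints = scene@inclusiveEndpoints)
    gate <- rep(0, n)
    t <- (seq_len(n) - 1) / scene@fs
    for (b in seq_len(nrow(bouts)))
      gate[t >= bouts[b, 1] & t < bouts[b, 2]] <- 1
    iq <- iq + wing * gate
    truthFw <- rep(fwSubject, nrow(bouts))
  }

  new("RadarRecording", iq = iq, fs = scene@fs, recordingId = recordingId,
      subjectId = subjectId, speciesName = profile@speciesName,
      truthBouts = bouts, truthFw = truthFw)
}

# Deterministic bout schedule mixing long and short flight bouts so that the
# duration sweep has material at every window length.
randomBoutSchedule <- function(durationS, seed, nBouts = 5,
                               lenRange = c(0.3, 8), gap = 1) {
  withSeed(seed, {
    bouts <- matrix(numeric(), ncol = 2)
    cursor <- runif(1, 0.5, 2)
    for (b in seq_len(nBouts)) {
      len <- exp(runif(1, log(lenRange[1]), log(lenRange[2])))
      if (cursor + len > durationS - 0.5) break
      bouts <- rbind(bouts, c(cursor, cursor + len))
      cursor <- cursor + len + runif(1, gap, 2 * gap)
    }
    bouts
  })
}

#' Default synthetic species profiles
#'
#' Five well-separated profiles, one per focal species, with fundamental
#' wingbeat means of 120/160/200/240/300 Hz, distinct harmonic envelopes,
#' 8 Hz between-subject SD and 15 dB wingbeat-to-noise ratio. These are
#' synthetic stand-ins chosen for testability, not calibrations to any real
#' recordings.
#'
#' @param snrDb wingbeat-to-noise power ratio applied to all profiles.
#' @return named list of [SpeciesProfile-class] objects.
#' @export
defaultSpeciesProfiles <- function(snrDb = 15) {
  # harmonic counts respect Nyquist at fs = 1 kHz for every subject draw:
  # N * (fwMean + 3*fwSd) < 500 Hz
  specs <- list(
    list("Bombus terrestris", 120, c(1.0, 0.6, 0.35)),
    list("Bombus lapidarius", 160, c(1.0, 0.35)),
    list("Bombus muscorum",   200, c(1.0, 0.55)),
    list("Apis mellifera",    240, c(1.0)),
    list("Vespula vulgaris",  300, c(1.0))
  )
  out <- lapply(specs, function(s)
    speciesProfile(speciesName = s[[1]], fwMean = s[[2]], fwSd = 8,
                   harmonicEnvelope = s[[3]], snrDb = snrDb))
  names(out) <- vapply(out, function(p) p@speciesName, character(1))
  out
}

#' Generate a labelled cohort of synthetic recordings
#'
#' Deterministically generates \code{nSubjectsPerSpecies} subjects for each
#' profile with \code{recordingsPerSubject} recordings each, assigning unique
#' subject IDs across species and a mixed-length bout schedule per recording.
#'
#' @param profiles list of [SpeciesProfile-class] objects.
#' @param nSubjectsPerSpecies subjects per species (>= 1).
#' @param recordingsPerSubject recordings per subject.
#' @param seed master seed; the same seed reproduces the cohort exactly.
#' @param durationS,fs recording length and sampling rate.
#' @param boutsPerRecording bouts scheduled per recording.
#' @return list with \code{recordings} (list of [RadarRecording-class]) and
#'   \code{manifest} (data.frame: recordingId, subjectId, species, truthFw,
#'   nBouts, flightS).
#' @export
generateCohort <- function(profiles, nSubjectsPerSpecies = 4,
                           recordingsPerSubject = 1, seed = 1,
                           durationS = 60, fs = 1000,
                           boutsPerRecording = 5) {
  stopifnot(nSubjectsPerSpecies >= 1)
  recs <- list()
  rows <- list()
  subjCounter <- 0L
  nTotal <- length(profiles) * nSubjectsPerSpecies * recordingsPerSubject
  seeds <- deriveSeeds(seed, 2L * nTotal)
  si <- 0L
  seen <- character(0)
  for (p in profiles) {
    for (s in seq_len(nSubjectsPerSpecies)) {
      subjCounter <- subjCounter + 1L
      subjectId <- sprintf("S%03d", subjCounter)
      if (subjectId %in% seen) stop("duplicate subject ID: ", subjectId)
      seen <- c(seen, subjectId)
      for (r in seq_len(recordingsPerSubject)) {
        si <- si + 1L
        bouts <- randomBoutSchedule(durationS, seeds[2L * si - 1L],
                                    nBouts = boutsPerRecording)
        scene <- sceneConfig(fs = fs, durationS = durationS,
                             boutSchedule = bouts, seed = seeds[2L * si])
        recId <- sprintf("%s_r%d", subjectId, r)
        rec <- synthesizeRecording(p, scene, subjectId, recordingId = recId)
        recs[[recId]] <- rec
        rows[[recId]] <- data.frame(
          recordingId = recId, subjectId = subjectId,
          species = p@speciesName,
          truthFw = if (length(rec@truthFw)) rec@truthFw[1] else NA_real_,
          nBouts = nrow(bouts),
          flightS = if (nrow(bouts)) sum(bouts[, 2] - bouts[, 1]) else 0,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  list(recordings = recs, manifest = manifest)
}

#' Simulate a cohort of standalone micro-Doppler segments
#'
#' Convenience generator for estimator benchmarking: \code{n} preprocessed
#' real-valued segments of wingbeat-plus-noise signal with known fundamental,
#' cycling over the supplied profiles. Each segment is built like a full
#' recording (wingbeat + noise + body motion), normalized, high-pass
#' filtered and channel-reduced exactly as the detection path does.
#'
#' @param n number of segments.
#' @param profiles species profiles to cycle over.
#' @param snrDb wingbeat-to-noise ratio (dB) overriding the profiles'.
#' @param durationS segment duration (s).
#' @param fs sampling rate.
#' @param seed master seed.
#' @param channel complex-to-real reduction (see
#'   [HarmonicRatioParams-class]).
#' @return list with \code{segments} ([SegmentSet-class]) and \code{truthFw}
#'   numeric vector.
#' @export
simulateSegmentCohort <- function(n = 200, profiles = defaultSpeciesProfiles(),
                                  snrDb = 20, durationS = 2, fs = 1000,
                                  seed = 1, channel = "real") {
  seeds <- deriveSeeds(seed, n)
  samples <- vector("list", n)
  truthFw <- numeric(n)
  species <- character(n)
  fspec <- filterSpec()
  for (i in seq_len(n)) {
    p <- profiles[[((i - 1L) %% length(profiles)) + 1L]]
    p@snrDb <- snrDb
    scene <- sceneConfig(fs = fs, durationS = durationS,
                         inclusiveEndpoints = FALSE,
                         boutSchedule = list(c(0, durationS)),
                         seed = seeds[i])
    rec <- synthesizeRecording(p, scene, sprintf("C%04d", i))
    x <- highpassFilter(normalizeIQ(rec@iq), fspec, fs)
    samples[[i]] <- channelSignal(x, channel)
    truthFw[i] <- rec@truthFw[1]
    species[i] <- p@speciesName
  }
  info <- data.frame(recordingId = sprintf("C%04d_r1", seq_len(n)),
                     subjectId = sprintf("C%04d", seq_len(n)),
                     species = species, startS = 0, durationS = durationS,
                     etaHr = NA_real_, stringsAsFactors = FALSE)
  # record the detection statistic for each simulated segment
  hp <- harmonicRatioParams(channel = channel)
  info$etaHr <- vapply(samples, function(s)
    harmonicRatio(s * hannWindow(length(s)), hp, fs), numeric(1))
  list(segments = new("SegmentSet", samples = samples, info = info, fs = fs),
       truthFw = truthFw)
}
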