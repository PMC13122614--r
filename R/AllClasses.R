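#' @import methods
NULL

# ---------------------------------------------------------------------------
# Synthesis-side classes
# ---------------------------------------------------------------------------

#' Wingbeat harmonic specification
#'
#' Describes the periodic wing-flap component of a micro-Doppler reflection as
#' a sum of \code{N} harmonics of a fundamental wingbeat frequency: harmonic
#' \code{n} contributes \code{A_n * exp(1i * (2*pi*n*fw*t + phi_n))}.
#'
#' @slot fw fundamental wingbeat frequency in Hz (> 0).
#' @slot amplitudes non-negative harmonic amplitudes \code{A_1..A_N}.
#' @slot phases harmonic phase offsets in radians, same length as
#'   \code{amplitudes}.
#' @slot jitterSd per-frame relative frequency jitter (dimensionless, >= 0);
#'   0 gives a strictly periodic component.
#' @export
setClass("WingbeatSpec", representation(
  fw = "numeric", amplitudes = "numeric", phases = "numeric",
  jitterSd = "numeric"
))

setValidity("WingbeatSpec", function(object) {
  msg <- character()
  if (length(object@fw) != 1 || !is.finite(object@fw) || object@fw <= 0)
    msg <- c(msg, "fw must be a single positive number")
  if (length(object@amplitudes) < 1)
    msg <- c(msg, "at least one harmonic is required")
  if (any(object@amplitudes < 0))
    msg <- c(msg, "harmonic amplitudes must be non-negative")
  if (length(object@phases) != length(object@amplitudes))
    msg <- c(msg, "phases and amplitudes must have the same length")
  if (length(object@jitterSd) != 1 || object@jitterSd < 0)
    msg <- c(msg, "jitterSd must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' @param fw fundamental wingbeat frequency (Hz).
#' @param amplitudes harmonic amplitudes \code{A_1..A_N}.
#' @param phases harmonic phases (radians); defaults to zeros.
#' @param jitterSd relative per-frame frequency jitter (>= 0).
#' @return A \code{WingbeatSpec} object.
#' @examples
#' wingbeatSpec(fw = 150, amplitudes = c(1, 0.5, 0.25))
#' @rdname WingbeatSpec-class
#' @export
wingbeatSpec <- function(fw, amplitudes = 1,
                         phases = rep(0, length(amplitudes)),
                         jitterSd = 0) {
  new("WingbeatSpec", fw = fw, amplitudes = as.numeric(amplitudes),
      phases = as.numeric(phases), jitterSd = jitterSd)
}

#' Species-level synthesis profile
#'
#' Population-level description of one species' micro-Doppler signature used
#' by the synthetic generator: the distribution of the fundamental wingbeat
#' frequency across subjects, the mean harmonic amplitude envelope with
#' per-subject multiplicative variation, the slow body-motion Doppler
#' component, and the wingbeat-to-noise power ratio.
#'
#' @slot speciesName species label (must appear in [taxonomyTable()]).
#' @slot fwMean,fwSd population mean and between-subject SD of the
#'   fundamental (Hz). \code{fwMean - 3*fwSd} must exceed 50 Hz so the
#'   wingbeat survives the high-pass filter.
#' @slot harmonicEnvelope mean harmonic amplitudes \code{A_1..A_N}.
#' @slot envelopeSubjectSd SD of the per-subject log-normal multiplicative
#'   variation applied to each harmonic amplitude.
#' @slot bodyMotionAmp,bodyMotionBandwidth RMS amplitude and bandwidth (Hz,
#'   < 50) of the slow Doppler component.
#' @slot snrDb wingbeat-to-noise power ratio in dB.
#' @export
setClass("SpeciesProfile", representation(
  speciesName = "character", fwMean = "numeric", fwSd = "numeric",
  harmonicEnvelope = "numeric", envelopeSubjectSd = "numeric",
  bodyMotionAmp = "numeric", bodyMotionBandwidth = "numeric",
  snrDb = "numeric"
))

setValidity("SpeciesProfile", function(object) {
  msg <- character()
  if (object@fwMean - 3 * object@fwSd <= 50)
    msg <- c(msg, "fwMean - 3*fwSd must exceed the 50 Hz high-pass cutoff")
  if (object@bodyMotionBandwidth >= 50)
    msg <- c(msg, "bodyMotionBandwidth must be below 50 Hz")
  if (any(object@harmonicEnvelope < 0))
    msg <- c(msg, "harmonicEnvelope must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @param speciesName,fwMean,fwSd,harmonicEnvelope,envelopeSubjectSd see slots.
#' @param bodyMotionAmp,bodyMotionBandwidth,snrDb see slots.
#' @return A \code{SpeciesProfile}.
#' @rdname SpeciesProfile-class
#' @export
speciesProfile <- function(speciesName, fwMean, fwSd = 8,
                           harmonicEnvelope = c(1, 0.5, 0.25),
                           envelopeSubjectSd = 0.15,
                           bodyMotionAmp = 0.5, bodyMotionBandwidth = 10,
                           snrDb = 15) {
  new("SpeciesProfile", speciesName = speciesName, fwMean = fwMean,
      fwSd = fwSd, harmonicEnvelope = as.numeric(harmonicEnvelope),
      envelopeSubjectSd = envelopeSubjectSd, bodyMotionAmp = bodyMotionAmp,
      bodyMotionBandwidth = bodyMotionBandwidth, snrDb = snrDb)
}

#' Recording scene configuration
#'
#' Sampling and scheduling parameters of one synthetic capture. The default
#' convention is 60 s at 1 kHz with inclusive endpoints, i.e. 60,001 samples
#' per recording.
#'
#' @slot fs sampling rate (samples/s).
#' @slot durationS recording length (s).
#' @slot inclusiveEndpoints if TRUE the sample grid includes both endpoints
#'   (n = fs*duration + 1 samples).
#' @slot boutSchedule two-column matrix of flight-bout (start, end) times in
#'   seconds; non-overlapping and within the recording.
#' @slot seed integer RNG seed for the recording.
#' @slot carrierGhz carrier frequency, metadata only.
#' @export
setClass("SceneConfig", representation(
  fs = "numeric", durationS = "numeric", inclusiveEndpoints = "logical",
  boutSchedule = "matrix", seed = "integer", carrierGhz = "numeric"
))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  b <- object@boutSchedule
  if (nrow(b)) {
    if (ncol(b) != 2) msg <- c(msg, "boutSchedule needs two columns")
    else {
      if (any(b[, 2] <= b[, 1])) msg <- c(msg, "bout end must exceed start")
      if (any(b < 0) || any(b > object@durationS))
        msg <- c(msg, "bouts must lie within [0, durationS]")
      if (nrow(b) > 1) {
        o <- order(b[, 1])
        if (any(b[o, 1][-1] < b[o, 2][-nrow(b)]))
          msg <- c(msg, "bouts must not overlap")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param fs,durationS,inclusiveEndpoints,boutSchedule,seed,carrierGhz see
#'   slots. \code{boutSchedule} may be given as a 2-column matrix or a list
#'   of \code{c(start, end)} pairs.
#' @return A \code{SceneConfig}.
#' @rdname SceneConfig-class
#' @export
sceneConfig <- function(fs = 1000, durationS = 60, inclusiveEndpoints = TRUE,
                        boutSchedule = list(), seed = 1L, carrierGhz = 30) {
  if (is.list(boutSchedule)) {
    boutSchedule <- if (length(boutSchedule))
      do.call(rbind, boutSchedule) else matrix(numeric(), ncol = 2)
  }
  storage.mode(boutSchedule) <- "double"
  new("SceneConfig", fs = fs, durationS = durationS,
      inclusiveEndpoints = inclusiveEndpoints, boutSchedule = boutSchedule,
      seed = as.integer(seed), carrierGhz = carrierGhz)
}

#' Complex baseband radar recording
#'
#' One down-converted continuous-wave capture: a complex I/Q sequence with
#' sampling metadata, subject/species labels and (for synthetic recordings)
#' ground-truth flight bouts and per-bout fundamental frequencies.
#'
#' @slot iq complex sample sequence.
#' @slot fs sampling rate (samples/s).
#' @slot recordingId,subjectId,speciesName identifiers.
#' @slot truthBouts two-column (start, end) matrix of true flight bouts (s).
#' @slot truthFw true fundamental (Hz) for each bout.
#' @export
setClass("RadarRecording", representation(
  iq = "complex", fs = "numeric", recordingId = "character",
  subjectId = "character", speciesName = "character",
  truthBouts = "matrix", truthFw = "numeric"
))

setValidity("RadarRecording", function(object) {
  msg <- character()
  if (!all(is.finite(Re(object@iq))) || !all(is.finite(Im(object@iq))))
    msg <- c(msg, "all I/Q samples must be finite")
  if (nrow(object@truthBouts) != length(object@truthFw))
    msg <- c(msg, "truthFw must have one entry per bout")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RadarRecording", function(object) {
  cat(sprintf("RadarRecording '%s': %d samples @ %g Hz (%.1f s)\n",
              object@recordingId, length(object@iq), object@fs,
              length(object@iq) / object@fs))
  cat(sprintf("  subject: %s   species: %s   bouts: %d\n",
              object@subjectId, object@speciesName, nrow(object@truthBouts)))
})

#' @describeIn RadarRecording-class the complex I/Q sequence.
#' @param x,object a \code{RadarRecording}.
#' @export
iqSignal <- function(x) x@iq

#' @describeIn RadarRecording-class sampling rate in samples/s.
#' @export
samplingRate <- function(x) x@fs

#' @describeIn RadarRecording-class ground-truth flight bouts (matrix).
#' @export
truthBouts <- function(x) x@truthBouts

# ---------------------------------------------------------------------------
# Preprocessing classes
# ---------------------------------------------------------------------------

#' High-pass filter specification
#'
#' Second-order Chebyshev type-I high-pass with a 50 Hz cutoff by default,
#' applied forward-backward (zero phase) to the I and Q channels identically.
#'
#' @slot family filter family; only \code{"chebyshev"} is supported.
#' @slot order filter order (>= 1).
#' @slot cutoffHz cutoff frequency in Hz.
#' @slot rippleDb passband ripple in dB.
#' @slot mode \code{"forward-backward"} (zero phase) or \code{"forward"}.
#' @export
setClass("FilterSpec", representation(
  family = "character", order = "numeric", cutoffHz = "numeric",
  rippleDb = "numeric", mode = "character"
))

setValidity("FilterSpec", function(object) {
  msg <- character()
  if (!identical(object@family, "chebyshev"))
    msg <- c(msg, "only the chebyshev family is supported")
  if (object@order < 1) msg <- c(msg, "order must be >= 1")
  if (object@cutoffHz <= 0) msg <- c(msg, "cutoffHz must be positive")
  if (!object@mode %in% c("forward", "forward-backward"))
    msg <- c(msg, "mode must be 'forward' or 'forward-backward'")
  if (length(msg)) msg else TRUE
})

#' @param family,order,cutoffHz,rippleDb,mode see slots.
#' @return A \code{FilterSpec}.
#' @rdname FilterSpec-class
#' @export
filterSpec <- function(family = "chebyshev", order = 2, cutoffHz = 50,
                       rippleDb = 1, mode = "forward-backward") {
  new("FilterSpec", family = family, order = order, cutoffHz = cutoffHz,
      rippleDb = rippleDb, mode = mode)
}

#' Framing specification
#'
#' Overlapping Hann-tapered analysis frames: 2 s frames with 1 s overlap by
#' default.
#'
#' @slot windowS frame length (s).
#' @slot overlapS overlap between consecutive frames (s); the hop is
#'   \code{windowS - overlapS}.
#' @export
setClass("FrameSpec", representation(windowS = "numeric", overlapS = "numeric"))

setValidity("FrameSpec", function(object) {
  if (object@overlapS <= 0 || object@overlapS >= object@windowS)
    "overlapS must satisfy 0 < overlapS < windowS" else TRUE
})

#' @param windowS,overlapS see slots.
#' @return A \code{FrameSpec}.
#' @rdname FrameSpec-class
#' @export
frameSpec <- function(windowS = 2, overlapS = 1) {
  new("FrameSpec", windowS = windowS, overlapS = overlapS)
}

# ---------------------------------------------------------------------------
# Detection classes
# ---------------------------------------------------------------------------

#' Harmonic-ratio detection parameters
#'
#' The harmonic ratio of a frame is the maximum of its normalized
#' autocorrelation over lags \code{[K0, K]} where \code{K = round(maxLagS*fs)}
#' (40 samples at 1 kHz, i.e. a 25 Hz minimum fundamental) and \code{K0} is
#' the first zero crossing of the autocorrelation.
#'
#' @slot maxLagS maximum autocorrelation lag in seconds (default 0.04).
#' @slot fallbackK0 lag used when the autocorrelation has no zero crossing.
#' @slot threshold retention threshold on the harmonic ratio (default 0.4).
#' @slot channel reduction of the complex signal to a real sequence:
#'   \code{"real"}, \code{"imag"} or \code{"magnitude"}.
#' @export
setClass("HarmonicRatioParams", representation(
  maxLagS = "numeric", fallbackK0 = "integer", threshold = "numeric",
  channel = "character"
))

setValidity("HarmonicRatioParams", function(object) {
  msg <- character()
  if (object@maxLagS <= 0) msg <- c(msg, "maxLagS must be positive")
  if (object@threshold < 0 || object@threshold > 1)
    msg <- c(msg, "threshold must lie in [0, 1]")
  if (!object@channel %in% c("real", "imag", "magnitude"))
    msg <- c(msg, "channel must be real, imag or magnitude")
  if (length(msg)) msg else TRUE
})

#' @param maxLagS,fallbackK0,threshold,channel see slots.
#' @return A \code{HarmonicRatioParams}.
#' @rdname HarmonicRatioParams-class
#' @export
harmonicRatioParams <- function(maxLagS = 0.04, fallbackK0 = 1L,
                                threshold = 0.4, channel = "real") {
  new("HarmonicRatioParams", maxLagS = maxLagS,
      fallbackK0 = as.integer(fallbackK0), threshold = threshold,
      channel = channel)
}

#' A set of detected micro-Doppler segments
#'
#' Fixed-duration real-valued analysis segments that passed harmonic-ratio
#' detection, with per-segment provenance.
#'
#' @slot samples list of real sample vectors, one per segment (the filtered,
#'   untapered channel signal; the Hann taper is applied only when computing
#'   the detection statistic).
#' @slot info data.frame with one row per segment: \code{recordingId},
#'   \code{subjectId}, \code{species}, \code{startS}, \code{durationS},
#'   \code{etaHr}.
#' @slot fs sampling rate (samples/s).
#' @export
setClass("SegmentSet", representation(
  samples = "list", info = "data.frame", fs = "numeric"
))

setValidity("SegmentSet", function(object) {
  msg <- character()
  if (length(object@samples) != nrow(object@info))
    msg <- c(msg, "samples and info must have matching lengths")
  need <- c("recordingId", "subjectId", "species", "startS", "durationS",
            "etaHr")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, paste("info must contain columns:",
                        paste(need, collapse = ", ")))
  if (nrow(object@info) &&
      (any(object@info$etaHr < 0) || any(object@info$etaHr > 1)))
    msg <- c(msg, "etaHr must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SegmentSet", function(object) {
  cat(sprintf("SegmentSet: %d segments @ %g Hz\n", length(object@samples),
              object@fs))
  if (nrow(object@info)) {
    d <- sort(unique(object@info$durationS))
    cat(sprintf("  durations (s): %s   species: %d   eta_HR range: %.2f-%.2f\n",
                paste(d, collapse = ", "),
                length(unique(object@info$species)),
                min(object@info$etaHr), max(object@info$etaHr)))
  }
})

#' @describeIn SegmentSet-class per-segment metadata data.frame.
#' @param x a \code{SegmentSet}.
#' @export
segmentInfo <- function(x) x@info

#' @describeIn SegmentSet-class list of per-segment sample vectors.
#' @export
segmentSamples <- function(x) x@samples

#' @describeIn SegmentSet-class number of segments.
#' @export
setMethod("length", "SegmentSet", function(x) length(x@samples))

# ---------------------------------------------------------------------------
# Feature classes
# ---------------------------------------------------------------------------

#' Mel-cepstral analysis specification
#'
#' Parameters of the MFCC block: a mel filterbank over \code{[filterbankLo,
#' filterbankHi]} Hz with \code{nBands} triangular bands, \code{nCoeffs}
#' cepstral coefficients (including the 0th), internal subframes whose length
#' is \code{segment duration / subframeDiv} with 50% hop, and a delta
#' regression window of \code{deltaWindow} subframes each side.
#'
#' @slot nCoeffs,filterbankLo,filterbankHi,nBands,subframeDiv,deltaWindow see
#'   description.
#' @export
setClass("MelSpec", representation(
  nCoeffs = "integer", filterbankLo = "numeric", filterbankHi = "numeric",
  nBands = "integer", subframeDiv = "integer", deltaWindow = "integer"
))

setValidity("MelSpec", function(object) {
  msg <- character()
  if (object@nCoeffs > object@nBands)
    msg <- c(msg, "nCoeffs must not exceed nBands")
  if (object@filterbankLo >= object@filterbankHi)
    msg <- c(msg, "filterbankLo must be below filterbankHi")
  if (length(msg)) msg else TRUE
})

#' @param nCoeffs,filterbankLo,filterbankHi,nBands,subframeDiv,deltaWindow
#'   see slots.
#' @return A \code{MelSpec}.
#' @rdname MelSpec-class
#' @export
melSpec <- function(nCoeffs = 14, filterbankLo = 0, filterbankHi = 500,
                    nBands = 26, subframeDiv = 8, deltaWindow = 2) {
  new("MelSpec", nCoeffs = as.integer(nCoeffs), filterbankLo = filterbankLo,
      filterbankHi = filterbankHi, nBands = as.integer(nBands),
      subframeDiv = as.integer(subframeDiv),
      deltaWindow = as.integer(deltaWindow))
}

#' Fundamental-frequency search specification
#'
#' Shared search range for the three wingbeat-fundamental estimators (pitch
#' estimation filter, continuous wavelet transform, normalized correlation
#' function), plus method internals.
#'
#' @slot fMin,fMax search range (Hz); below 50 Hz nothing survives the
#'   high-pass filter, above ~400 Hz harmonics approach Nyquist at 1 kHz.
#' @slot gridHz candidate spacing for PEF/CWT scans (Hz).
#' @slot waveletOmega0 Morlet wavelet centre frequency (rad).
#' @slot minQualityPef,minQualityWt peak-prominence ratios (peak score over
#'   median score across candidates) below which a PEF or wavelet estimate
#'   is flagged missing; the null (noise-only) ratio distributions of the
#'   two methods differ, hence separate thresholds.
#' @export
setClass("F0SearchSpec", representation(
  fMin = "numeric", fMax = "numeric", gridHz = "numeric",
  waveletOmega0 = "numeric", minQualityPef = "numeric",
  minQualityWt = "numeric"
))

setValidity("F0SearchSpec", function(object) {
  if (object@fMin < 25 || object@fMin >= object@fMax)
    "need 25 <= fMin < fMax" else TRUE
})

#' @param fMin,fMax,gridHz,waveletOmega0,minQualityPef,minQualityWt see
#'   slots.
#' @return An \code{F0SearchSpec}.
#' @rdname F0SearchSpec-class
#' @export
f0SearchSpec <- function(fMin = 50, fMax = 400, gridHz = 1,
                         waveletOmega0 = 6, minQualityPef = 20,
                         minQualityWt = 4) {
  new("F0SearchSpec", fMin = fMin, fMax = fMax, gridHz = gridHz,
      waveletOmega0 = waveletOmega0, minQualityPef = minQualityPef,
      minQualityWt = minQualityWt)
}

#' Feature registry
#'
#' Ordered definition of the per-segment feature vector. The default registry
#' (see [defaultFeatureRegistry()]) emits exactly 70 named features: 14
#' static MFCCs + 14 deltas + 14 delta-deltas, three fundamental-frequency
#' estimates (\code{PEF_F0}, \code{WT_F0}, \code{NCF_F0}), the detection
#' \code{HarmonicRatio}, nine 50-Hz band-power ratios between 50 and 500 Hz,
#' and 15 spectral/temporal descriptors.
#'
#' @slot entries data.frame with columns \code{name} and \code{block}.
#' @slot expectedTotal required number of features (70 by default).
#' @slot melSpec a [MelSpec-class] parameter block.
#' @slot f0Spec an [F0SearchSpec-class] parameter block.
#' @slot bands two-column matrix of band-power (lo, hi) edges in Hz.
#' @export
setClass("FeatureRegistry", representation(
  entries = "data.frame", expectedTotal = "integer", melSpec = "MelSpec",
  f0Spec = "F0SearchSpec", bands = "matrix"
))

setValidity("FeatureRegistry", function(object) {
  msg <- character()
  if (anyDuplicated(object@entries$name))
    msg <- c(msg, "feature names must be unique")
  if (nrow(object@entries) != object@expectedTotal)
    msg <- c(msg, sprintf("registry defines %d features but expectedTotal is %d",
                          nrow(object@entries), object@expectedTotal))
  if (length(msg)) msg else TRUE
})

setMethod("show", "FeatureRegistry", function(object) {
  cat(sprintf("FeatureRegistry: %d features in %d blocks\n",
              nrow(object@entries), length(unique(object@entries$block))))
})

#' @describeIn FeatureRegistry-class ordered feature names.
#' @param x a \code{FeatureRegistry}.
#' @export
featureNames <- function(x) x@entries$name

# ---------------------------------------------------------------------------
# Cascade classes
# ---------------------------------------------------------------------------

#' Hierarchical cascade model
#'
#' Three trained stages: a gradient-boosted tree ensemble separating the
#' families Vespidae/Apidae, a gradient-boosted ensemble separating the
#' Apidae genera Apis/Bombus, and an extremely-randomized-trees ensemble
#' separating the three Bombus species. Stage-1 Vespidae predictions map
#' directly to Vespula vulgaris and stage-2 Apis predictions to Apis
#' mellifera.
#'
#' @slot stage1,stage2,stage3 fitted stage models.
#' @slot featureNames feature column order used at fit time.
#' @slot classLevels list of class label vectors per stage.
#' @slot classWeights list of per-class weight vectors per stage.
#' @slot taxonomy the species/genus/family table used.
#' @slot config hyperparameters and seed.
#' @export
setClass("CascadeModel", representation(
  stage1 = "ANY", stage2 = "ANY", stage3 = "ANY",
  featureNames = "character", classLevels = "list", classWeights = "list",
  taxonomy = "data.frame", config = "list"
))

setMethod("show", "CascadeModel", function(object) {
  cat("CascadeModel (family -> genus -> species)\n")
  cat(sprintf("  stage1: boosted trees  [%s]\n",
              paste(object@classLevels$family, collapse = " vs ")))
  cat(sprintf("  stage2: boosted trees  [%s]\n",
              paste(object@classLevels$genus, collapse = " vs ")))
  cat(sprintf("  stage3: extra-trees    [%s]\n",
              paste(object@classLevels$species3, collapse = ", ")))
  cat(sprintf("  features: %d\n", length(object@featureNames)))
})

#' Cascade evaluation report
#'
#' Cumulative confusion matrices at family, genus and species granularity
#' (classes finalized in earlier stages are carried forward), per-species
#' precision/recall/F1, overall accuracy and the micro-averaged F1.
#'
#' @slot confusion list of confusion matrices (\code{family}, \code{genus},
#'   \code{species}); rows are truth, columns predictions.
#' @slot metrics per-species data.frame with precision, recall, F1.
#' @slot accuracy species-level accuracy (trace / total).
#' @slot stageAccuracy named numeric: cumulative accuracy at each level.
#' @slot microF1 micro-averaged F1 (equals accuracy for single-label data).
#' @slot nTest number of evaluated samples.
#' @export
setClass("CascadeEvaluation", representation(
  confusion = "list", metrics = "data.frame", accuracy = "numeric",
  stageAccuracy = "numeric", microF1 = "numeric", nTest = "integer"
))

setMethod("show", "CascadeEvaluation", function(object) {
  cat(sprintf("CascadeEvaluation: n = %d\n", object@nTest))
  cat(sprintf("  accuracy: family %.3f | genus %.3f | species %.3f\n",
              object@stageAccuracy["family"], object@stageAccuracy["genus"],
              object@stageAccuracy["species"]))
  print(round(object@metrics, 3))
})

# ---------------------------------------------------------------------------
# Attribution classes
# ---------------------------------------------------------------------------

#' Additive feature attributions
#'
#' Per-feature Shapley attributions of model outputs: for every explained
#' instance, \code{baseValue + sum(values)} equals the model output
#' (efficiency axiom).
#'
#' @slot values matrix (instances x features) of signed attributions.
#' @slot baseValues expected model output over the background set, per
#'   instance (identical across instances for a fixed background).
#' @slot predictions model outputs for the explained instances.
#' @slot featureNames explained feature names.
#' @export
setClass("AttributionResult", representation(
  values = "matrix", baseValues = "numeric", predictions = "numeric",
  featureNames = "character"
))

setValidity("AttributionResult", function(object) {
  if (ncol(object@values) != length(object@featureNames))
    "values must have one column per feature" else TRUE
})

setMethod("show", "AttributionResult", function(object) {
  cat(sprintf("AttributionResult: %d instances x %d features\n",
              nrow(object@values), ncol(object@values)))
  imp <- sort(colMeans(abs(object@values)), decreasing = TRUE)
  cat("  top features by mean |attribution|:\n")
  print(round(utils::head(imp, 5), 4))
})

#' @describeIn AttributionResult-class attribution matrix.
#' @param x an \code{AttributionResult}.
#' @export
attributionValues <- function(x) x@values

#' @describeIn AttributionResult-class per-instance base values.
#' @export
baseValues <- function(x) x@baseValues
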