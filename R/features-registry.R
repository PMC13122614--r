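# The 70-feature registry and segment-to-feature-vector extraction.

canonicalFeatureNames <- function() {
  c("mfccDelta1", "WT_F0", "PEF_F0", "NCF_F0", "HarmonicRatio",
    "bandPower_100_150", "bandPower_250_300", "bandPower_300_350",
    "bandPower_400_450", "mfcc0", "mfcc1", "mfcc3", "mfcc7",
    "mfccDelta5", "mfccDelta7", "mfccDeltaDelta0", "mfccDeltaDelta1",
    "mfccDeltaDelta3", "mfccDeltaDelta5", "mfccDeltaDelta7")
}

#' Construct a feature registry
#'
#' @param entries data.frame with columns \code{name}, \code{block}.
#' @param expectedTotal required feature count (70 for the default layout).
#' @param melSpec,f0Spec,bands parameter blocks, see
#'   [FeatureRegistry-class].
#' @return A [FeatureRegistry-class].
#' @export
featureRegistry <- function(entries, expectedTotal = 70L,
                            melSpec = wingbeatRadar::melSpec(),
                            f0Spec = f0SearchSpec(),
                            bands = defaultBands()) {
  new("FeatureRegistry", entries = entries,
      expectedTotal = as.integer(expectedTotal), melSpec = melSpec,
      f0Spec = f0Spec, bands = bands)
}

#' The default 70-feature registry
#'
#' 14 static MFCCs + 14 deltas + 14 delta-deltas (42), three
#' fundamental-frequency estimates (\code{PEF_F0}, \code{WT_F0},
#' \code{NCF_F0}), the \code{HarmonicRatio} detection statistic, nine 50-Hz
#' band-power ratios over 50-500 Hz, and 15 spectral/temporal descriptors:
#' 70 features in total. The registry is configuration-driven, so an
#' alternative feature table can be supplied through [featureRegistry()];
#' the count invariant is enforced at validation.
#'
#' @inheritParams featureRegistry
#' @return A [FeatureRegistry-class] with exactly 70 entries.
#' @examples
#' reg <- defaultFeatureRegistry()
#' length(featureNames(reg))  # 70
#' @export
defaultFeatureRegistry <- function(melSpec = wingbeatRadar::melSpec(),
                                   f0Spec = f0SearchSpec(),
                                   bands = defaultBands()) {
  k <- seq_len(melSpec@nCoeffs) - 1
  mfccNames <- c(paste0("mfcc", k), paste0("mfccDelta", k),
                 paste0("mfccDeltaDelta", k))
  bandNames <- sprintf("bandPower_%d_%d", as.integer(bands[, 1]),
                       as.integer(bands[, 2]))
  specTempNames <- c("spectralCentroid", "spectralSpread",
                     "spectralSkewness", "spectralKurtosis",
                     "spectralFlatness", "spectralEntropy", "spectralCrest",
                     "spectralRolloff", "spectralSlope", "spectralDecrease",
                     "spectralFlux", "peakFrequency", "rmsEnergy",
                     "zeroCrossRate", "temporalCrest")
  entries <- data.frame(
    name = c(mfccNames, "PEF_F0", "WT_F0", "NCF_F0", "HarmonicRatio",
             bandNames, specTempNames),
    block = c(rep("mfcc", length(mfccNames)), rep("f0", 3), "harmonicratio",
              rep("bandpower", length(bandNames)),
              rep("spectemp", length(specTempNames))),
    stringsAsFactors = FALSE)
  missing <- setdiff(canonicalFeatureNames(), entries$name)
  if (length(missing))
    stop("registry is missing canonical features: ",
         paste(missing, collapse = ", "))
  featureRegistry(entries, expectedTotal = nrow(entries), melSpec = melSpec,
                  f0Spec = f0Spec, bands = bands)
}

# Compute the registry's feature vector for one segment.
featureVectorForSegment <- function(x, etaHr, registry, fs) {
  blocks <- unique(registry@entries$block)
  vals <- c()
  if ("mfcc" %in% blocks)
    vals <- c(vals, mfccBlock(x, registry@melSpec, fs))
  if ("f0" %in% blocks) {
    ncf <- estimateF0Ncf(x, registry@f0Spec, fs)
    pef <- estimateF0Pef(x, registry@f0Spec, fs)
    wt <- estimateF0Wavelet(x, registry@f0Spec, fs)
    # imputation: failed PEF/WT estimates fall back to the NCF estimate,
    # and a failed NCF to fMin, so the vector stays fully finite
    ncfImp <- if (is.na(ncf)) registry@f0Spec@fMin else ncf
    vals <- c(vals, PEF_F0 = if (is.na(pef)) ncfImp else pef,
              WT_F0 = if (is.na(wt)) ncfImp else wt, NCF_F0 = ncfImp)
  }
  if ("harmonicratio" %in% blocks)
    vals <- c(vals, HarmonicRatio = etaHr)
  if ("bandpower" %in% blocks)
    vals <- c(vals, bandPowerRatios(x, registry@bands, fs))
  if ("spectemp" %in% blocks)
    vals <- c(vals, spectralTemporalBlock(x, fs))
  vals
}

#' Extract the feature table of a segment set
#'
#' Runs every registry block on every segment and assembles a
#' \code{SummarizedExperiment} with one assay \code{"features"} (features in
#' rows, segments in columns) and the per-segment metadata as
#' \code{colData}. The \code{HarmonicRatio} feature is copied from the
#' segment's detection statistic. All values are guaranteed finite (failed
#' fundamental estimates are imputed, see [estimateF0Ncf()]).
#'
#' @param segments a [SegmentSet-class].
#' @param registry a [FeatureRegistry-class].
#' @return A \code{SummarizedExperiment} with \code{expectedTotal} rows.
#' @export
extractFeatures <- function(segments, registry = defaultFeatureRegistry()) {
  validObject(registry)
  fs <- segments@fs
  info <- segmentInfo(segments)
  n <- length(segments)
  wanted <- registry@entries$name
  M <- matrix(NA_real_, nrow = length(wanted), ncol = n,
              dimnames = list(wanted, NULL))
  for (i in seq_len(n)) {
    v <- featureVectorForSegment(segmentSamples(segments)[[i]],
                                 info$etaHr[i], registry, fs)
    if (!all(wanted %in% names(v)))
      stop("extractors did not produce features: ",
           paste(setdiff(wanted, names(v)), collapse = ", "))
    M[, i] <- v[wanted]
  }
  if (n && !all(is.finite(M)))
    stop("non-finite feature values after imputation")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = M),
    colData = S4Vectors::DataFrame(info))
}
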