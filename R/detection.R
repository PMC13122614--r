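# Harmonic-ratio detection of wing-flap (micro-Doppler) segments.
#
# The statistic: for a real frame x of length L, the normalized
# autocorrelation Psi(k) compares the frame with its k-lagged copy,
# normalized by the energies of the two overlapping sub-windows, so
# Psi(k) in [-1, 1]. The harmonic ratio eta_HR is the maximum of Psi over
# the lag interval [K0, K] where K = round(0.04 * fs) (a 25 Hz minimum
# fundamental) and K0 adapts per frame to the first zero crossing of Psi.

#' Normalized autocorrelation of a frame
#'
#' \code{Psi(k) = sum(x[n] x[n+k]) / sqrt(sum(x[n]^2) * sum(x[n+k]^2))}
#' with sums over the overlapping part, for lags \code{k = 1..K}. Zero-energy
#' sub-windows yield \code{Psi(k) = 0}.
#'
#' @param frame real sample vector of length > K.
#' @param K maximum lag in samples.
#' @return numeric vector of length K, values in \code{[-1, 1]}.
#' @export
normalizedAutocorrelation <- function(frame, K) {
  L <- length(frame)
  if (K >= L) stop("K must be smaller than the frame length")
  stopifnotFinite(frame, "frame")
  psi <- numeric(K)
  for (k in seq_len(K)) {
    a <- frame[seq_len(L - k)]
    b <- frame[(k + 1L):L]
    denom <- sqrt(sum(a^2) * sum(b^2))
    psi[k] <- if (denom == 0) 0 else sum(a * b) / denom
  }
  psi
}

#' First zero crossing of the autocorrelation
#'
#' Returns the smallest lag \code{k > 0} with
#' \code{Psi(k-1) * Psi(k) <= 0}, taking \code{Psi(0) = 1}. When no such
#' lag exists the supplied fallback is returned.
#'
#' @param psi autocorrelation values at lags \code{1..K}.
#' @param fallbackK0 lag returned when there is no zero crossing.
#' @return integer lag.
#' @export
firstZeroCrossing <- function(psi, fallbackK0 = 1L) {
  if (!length(psi)) stop("empty psi")
  prev <- c(1, psi[-length(psi)])
  hit <- which(prev * psi <= 0)
  if (length(hit)) hit[1L] else as.integer(fallbackK0)
}

#' Harmonic ratio of a frame
#'
#' \code{eta_HR = clamp(max_{k in [K0, K]} Psi(k), 0, 1)} with
#' \code{K = round(maxLagS * fs)}. A degenerate (zero-variance) frame has
#' \code{eta_HR = 0}.
#'
#' @param frame real sample vector.
#' @param params a [HarmonicRatioParams-class].
#' @param fs sampling rate.
#' @return scalar in \code{[0, 1]}.
#' @export
harmonicRatio <- function(frame, params = harmonicRatioParams(), fs) {
  validObject(params)
  K <- as.integer(round(params@maxLagS * fs))
  if (K < 1L) stop("maxLagS too small for this sampling rate")
  if (stats::var(frame) == 0) return(0)
  psi <- normalizedAutocorrelation(frame, K)
  K0 <- firstZeroCrossing(psi, params@fallbackK0)
  clamp(max(psi[K0:K]), 0, 1)
}

# Shared preprocessing for the detection entry points.
preprocessForDetection <- function(recording, filterSpec, channel) {
  x <- normalizeIQ(recording@iq)
  x <- highpassFilter(x, filterSpec, recording@fs)
  channelSignal(x, channel)
}

makeSegmentSet <- function(recording, sig, starts, L, eta, fs, keep) {
  starts <- starts[keep]; eta <- eta[keep]
  samples <- lapply(starts, function(s) sig[(s + 1L):(s + L)])
  info <- data.frame(
    recordingId = rep(recording@recordingId, length(starts)),
    subjectId = rep(recording@subjectId, length(starts)),
    species = rep(recording@speciesName, length(starts)),
    startS = starts / fs, durationS = rep(L / fs, length(starts)),
    etaHr = eta,
    stringsAsFactors = FALSE)
  new("SegmentSet", samples = samples, info = info, fs = fs)
}

#' Detect micro-Doppler segments in a recording
#'
#' Normalizes and high-pass filters the recording, reduces it to a real
#' channel, computes the harmonic ratio of every overlapping Hann frame and
#' retains the frames whose \code{eta_HR} exceeds the threshold. One
#' retained segment per qualifying frame; the stored samples are the
#' filtered, untapered channel signal.
#'
#' @param recording a [RadarRecording-class].
#' @param frameSpec a [FrameSpec-class] (2 s window, 1 s overlap default).
#' @param hrParams a [HarmonicRatioParams-class].
#' @param filterSpec a [FilterSpec-class].
#' @return A [SegmentSet-class] (possibly empty).
#' @export
detectSegments <- function(recording, frameSpec = wingbeatRadar::frameSpec(),
                           hrParams = harmonicRatioParams(),
                           filterSpec = wingbeatRadar::filterSpec()) {
  fs <- recording@fs
  sig <- preprocessForDetection(recording, filterSpec, hrParams@channel)
  fr <- frameSignal(sig, frameSpec, fs, taper = TRUE)
  L <- fr$windowSamples
  eta <- vapply(fr$frames, harmonicRatio, numeric(1),
                params = hrParams, fs = fs)
  starts <- as.integer(round(fr$startS * fs))
  makeSegmentSet(recording, sig, starts, L, eta, fs,
                 keep = eta > hrParams@threshold)
}

#' Re-segment a recording at multiple window durations
#'
#' Scans the preprocessed recording with windows of each requested duration
#' at 50% overlap and retains windows whose harmonic ratio exceeds the
#' threshold. With \code{exclusive = TRUE} (the duration-sweep convention)
#' durations are processed longest-first and each region of signal
#' contributes only at the longest duration for which it qualifies: a
#' window overlapping samples already claimed at a longer duration is
#' skipped. With \code{exclusive = FALSE} every duration is scanned
#' independently (the convention matching per-duration segment tallies).
#'
#' @param recording a [RadarRecording-class].
#' @param durations window lengths in seconds, sorted descending.
#' @param hrParams a [HarmonicRatioParams-class].
#' @param filterSpec a [FilterSpec-class].
#' @param exclusive claim each signal region at its longest qualifying
#'   duration only.
#' @return named list \code{duration -> SegmentSet}.
#' @export
resegmentDurations <- function(recording,
                               durations = c(2, 1, 0.8, 0.6, 0.4, 0.2, 0.1),
                               hrParams = harmonicRatioParams(),
                               filterSpec = wingbeatRadar::filterSpec(),
                               exclusive = TRUE) {
  if (is.unsorted(rev(durations)))
    stop("durations must be sorted descending")
  fs <- recording@fs
  if (any(round(durations * fs) < 2))
    stop("durations must span at least 2 samples")
  sig <- preprocessForDetection(recording, filterSpec, hrParams@channel)
  n <- length(sig)
  claimed <- rep(FALSE, n)
  K <- as.integer(round(hrParams@maxLagS * fs))
  out <- list()
  for (d in durations) {
    L <- as.integer(round(d * fs))
    if (L <= K)
      stop("duration ", d, " s gives ", L,
           " samples, not larger than the maximum lag K = ", K)
    hop <- max(1L, as.integer(round(L / 2)))
    nFrames <- if (n < L) 0L else floor((n - L) / hop) + 1L
    starts <- (seq_len(nFrames) - 1L) * hop
    w <- hannWindow(L)
    eta <- numeric(nFrames)
    keep <- logical(nFrames)
    for (i in seq_len(nFrames)) {
      idx <- (starts[i] + 1L):(starts[i] + L)
      if (exclusive && any(claimed[idx])) next
      eta[i] <- harmonicRatio(sig[idx] * w, hrParams, fs)
      if (eta[i] > hrParams@threshold) {
        keep[i] <- TRUE
        if (exclusive) claimed[idx] <- TRUE
      }
    }
    out[[as.character(d)]] <-
      makeSegmentSet(recording, sig, starts, L, eta, fs, keep)
  }
  out
}

#' Combine segment sets
#'
#' Concatenates several [SegmentSet-class] objects (e.g. across the
#' recordings of a cohort) into one.
#'
#' @param sets list of \code{SegmentSet} objects with a common sampling rate.
#' @return A [SegmentSet-class].
#' @export
combineSegments <- function(sets) {
  sets <- Filter(function(s) length(s) > 0, sets)
  if (!length(sets))
    return(new("SegmentSet", samples = list(),
               info = data.frame(recordingId = character(),
                                 subjectId = character(),
                                 species = character(), startS = numeric(),
                                 durationS = numeric(), etaHr = numeric(),
                                 stringsAsFactors = FALSE),
               fs = NA_real_))
  fs <- unique(vapply(sets, function(s) s@fs, numeric(1)))
  if (length(fs) != 1) stop("segment sets have differing sampling rates")
  info <- do.call(rbind, lapply(sets, segmentInfo))
  rownames(info) <- NULL
  new("SegmentSet", samples = do.call(c, lapply(sets, segmentSamples)),
      info = info, fs = fs)
}
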