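# Band-power ratios and spectral/temporal shape descriptors.

#' Band-power ratios of a segment
#'
#' For each band \code{[lo, hi)} the fraction of total one-sided Hann
#' periodogram power falling inside the band. Fractions lie in
#' \code{[0, 1]}; over any set of disjoint bands they sum to at most 1.
#'
#' @param x real sample vector.
#' @param bands two-column matrix (or list of \code{c(lo, hi)}) in Hz.
#' @param fs sampling rate.
#' @return named numeric vector \code{bandPower_{lo}_{hi}}.
#' @export
bandPowerRatios <- function(x, bands = defaultBands(), fs) {
  if (is.list(bands)) bands <- do.call(rbind, bands)
  pg <- periodogramOneSided(x, fs, "hann")
  total <- sum(pg$power)
  out <- apply(bands, 1, function(b) {
    if (total == 0) return(0)
    sum(pg$power[pg$freq >= b[1] & pg$freq < b[2]]) / total
  })
  names(out) <- sprintf("bandPower_%d_%d", as.integer(bands[, 1]),
                        as.integer(bands[, 2]))
  out
}

#' Default band-power bands
#'
#' Nine contiguous 50-Hz bands covering 50-500 Hz.
#' @return a 9 x 2 matrix of (lo, hi) band edges in Hz.
#' @export
defaultBands <- function() {
  lo <- seq(50, 450, by = 50)
  cbind(lo, lo + 50)
}

#' Spectral and temporal shape descriptors
#'
#' Fifteen standard descriptors of a segment. Spectral descriptors are
#' moments and shape statistics of the one-sided Hann periodogram
#' \code{P(f)} treated as a distribution over frequency: centroid
#' \code{sum(f P)/sum(P)}, spread (standard deviation about the centroid),
#' skewness and excess kurtosis (standardized 3rd/4th moments), flatness
#' (geometric/arithmetic mean of P), normalized spectral entropy, crest
#' (max/mean of P), 85% rolloff frequency, linear regression slope of P on
#' f, spectral decrease, and spectral flux (mean L2 change of the
#' normalized spectrum across eight half-overlapping subframes). Temporal
#' descriptors: peak frequency (argmax P), RMS energy, zero-crossing rate
#' per second, and temporal crest factor \code{max|x|/rms}.
#'
#' @param x real sample vector.
#' @param fs sampling rate.
#' @return named numeric vector of 15 descriptors.
#' @export
spectralTemporalBlock <- function(x, fs) {
  pg <- periodogramOneSided(x, fs, "hann")
  f <- pg$freq; P <- pg$power
  tot <- sum(P)
  if (tot == 0) {
    p <- rep(0, length(P)); centroid <- 0; spread <- 0
    skew <- 0; kurt <- 0
  } else {
    p <- P / tot
    centroid <- sum(f * p)
    spread <- sqrt(sum((f - centroid)^2 * p))
    skew <- if (spread > 0) sum(((f - centroid) / spread)^3 * p) else 0
    kurt <- if (spread > 0) sum(((f - centroid) / spread)^4 * p) - 3 else 0
  }
  Ppos <- P[P > 0]
  flat <- if (length(Ppos)) exp(mean(log(Ppos))) / mean(Ppos) else 0
  ent <- if (tot > 0) {
    q <- p[p > 0]
    -sum(q * log(q)) / log(length(P))
  } else 0
  crest <- if (tot > 0) max(P) / mean(P) else 0
  roll <- if (tot > 0) f[which(cumsum(p) >= 0.85)[1]] else 0
  slope <- if (tot > 0) {
    fc <- f - mean(f)
    sum(fc * (P - mean(P))) / sum(fc^2)
  } else 0
  decrease <- if (tot > 0 && length(P) > 1) {
    k <- seq_along(P)[-1]
    den <- sum(P[k])
    if (den > 0) sum((P[k] - P[1]) / (k - 1)) / den else 0
  } else 0

  # flux over 8 half-overlapping subframes of the segment
  flux <- {
    Lsub <- max(4L, floor(2 * length(x) / 9))
    hop <- max(1L, floor(Lsub / 2))
    nSub <- max(1L, floor((length(x) - Lsub) / hop) + 1L)
    if (nSub < 2L) 0 else {
      specs <- vapply(seq_len(nSub), function(t) {
        seg <- x[((t - 1L) * hop + 1L):((t - 1L) * hop + Lsub)]
        s <- periodogramOneSided(seg, fs, "hann")$power
        tt <- sum(s)
        if (tt > 0) s / tt else s
      }, numeric(floor(Lsub / 2) + 1L))
      mean(sqrt(colSums((specs[, -1, drop = FALSE] -
                           specs[, -nSub, drop = FALSE])^2)))
    }
  }

  rms <- sqrt(mean(x^2))
  zcr <- if (length(x) > 1) sum(diff(sign(x)) != 0) / (length(x) / fs) else 0
  tcrest <- if (rms > 0) max(abs(x)) / rms else 0

  c(spectralCentroid = centroid, spectralSpread = spread,
    spectralSkewness = skew, spectralKurtosis = kurt,
    spectralFlatness = flat, spectralEntropy = ent, spectralCrest = crest,
    spectralRolloff = roll, spectralSlope = slope,
    spectralDecrease = decrease, spectralFlux = flux,
    peakFrequency = f[which.max(P)], rmsEnergy = rms,
    zeroCrossRate = zcr, temporalCrest = tcrest)
}
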