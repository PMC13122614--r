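# Mel-frequency cepstral coefficients with delta and delta-delta dynamics.
#
# At fs = 1 kHz the filterbank spans 0-500 Hz with 26 triangular mel bands.
# A segment is analysed in internal subframes of length duration/subframeDiv
# with 50% hop (0.25 s / 0.125 s for a 2 s segment), which scales down
# proportionally for shorter segments so the delta features stay defined at
# every supported duration; segments yielding fewer than 4 subframes are
# zero-padded. Coefficients are aggregated over subframes by the mean.

hzToMel <- function(f) 2595 * log10(1 + f / 700)
melToHz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank evaluated on the one-sided FFT bin frequencies.
melFilterbank <- function(nBands, lo, hi, binFreqs) {
  pts <- melToHz(seq(hzToMel(lo), hzToMel(hi), length.out = nBands + 2))
  fb <- matrix(0, nBands, length(binFreqs))
  for (b in seq_len(nBands)) {
    l <- pts[b]; c <- pts[b + 1]; r <- pts[b + 2]
    up <- (binFreqs - l) / (c - l)
    down <- (r - binFreqs) / (r - c)
    fb[b, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix (nCoeffs x nBands).
dctMatrix <- function(nCoeffs, nBands) {
  m <- outer(seq_len(nCoeffs) - 1, seq_len(nBands) - 0.5,
             function(k, j) cos(pi * k * j / nBands))
  m <- m * sqrt(2 / nBands)
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

# Regression-slope deltas over +/- W subframes (replicated edges).
deltaCoefficients <- function(C, W) {
  # C: nCoeffs x nSub matrix
  nSub <- ncol(C)
  denom <- 2 * sum(seq_len(W)^2)
  idx <- function(i) pmin(pmax(i, 1L), nSub)
  D <- matrix(0, nrow(C), nSub)
  for (t in seq_len(nSub)) {
    acc <- 0
    for (nn in seq_len(W))
      acc <- acc + nn * (C[, idx(t + nn)] - C[, idx(t - nn)])
    D[, t] <- acc / denom
  }
  D
}

# Per-subframe MFCC matrix for a real segment.
mfccMatrix <- function(x, spec, fs) {
  L <- length(x)
  Lsub <- max(4L, round(L / spec@subframeDiv))
  hop <- max(1L, round(Lsub / 2))
  nSub <- if (L < Lsub) 0L else floor((L - Lsub) / hop) + 1L
  if (nSub < 4L) {
    need <- Lsub + (4L - 1L) * hop
    x <- c(x, rep(0, need - L))
    nSub <- 4L
  }
  nfft <- max(256L, 2^ceiling(log2(Lsub)))
  half <- nfft / 2 + 1L
  binFreqs <- (seq_len(half) - 1) * fs / nfft
  fb <- melFilterbank(spec@nBands, spec@filterbankLo,
                      min(spec@filterbankHi, fs / 2), binFreqs)
  dct <- dctMatrix(spec@nCoeffs, spec@nBands)
  w <- hannWindow(Lsub)
  E <- matrix(0, spec@nBands, nSub)
  for (t in seq_len(nSub)) {
    seg <- x[((t - 1L) * hop + 1L):((t - 1L) * hop + Lsub)] * w
    X <- fft(c(seg, rep(0, nfft - Lsub)))
    E[, t] <- fb %*% (Mod(X[seq_len(half)])^2)
  }
  # relative floor keeps the log defined and preserves scale invariance
  floorVal <- max(E) * 1e-12
  if (floorVal == 0) return(matrix(0, spec@nCoeffs, nSub))
  dct %*% log(pmax(E, floorVal))
}

#' MFCC feature block of a segment
#'
#' Computes per-subframe mel-frequency cepstral coefficients on the
#' magnitude spectrum, their regression-slope deltas and delta-deltas, and
#' aggregates each coefficient over subframes by the mean. Emits names
#' \code{mfcc0..mfcc{n-1}}, \code{mfccDelta0..}, \code{mfccDeltaDelta0..}.
#'
#' @param x real sample vector (one segment).
#' @param spec a [MelSpec-class].
#' @param fs sampling rate.
#' @return named numeric vector of \code{3 * nCoeffs} values.
#' @export
mfccBlock <- function(x, spec = melSpec(), fs) {
  validObject(spec)
  if (length(x) < 4L) stop("segment shorter than one subframe")
  C <- mfccMatrix(x, spec, fs)
  D <- deltaCoefficients(C, spec@deltaWindow)
  DD <- deltaCoefficients(D, spec@deltaWindow)
  k <- seq_len(spec@nCoeffs) - 1
  out <- c(rowMeans(C), rowMeans(D), rowMeans(DD))
  names(out) <- c(paste0("mfcc", k), paste0("mfccDelta", k),
                  paste0("mfccDeltaDelta", k))
  out
}
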