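# Three independent estimators of the fundamental wingbeat frequency.
#
# All three search [fMin, fMax] (50-400 Hz by default: below the high-pass
# cutoff nothing survives, and above ~400 Hz the harmonics approach Nyquist
# at 1 kHz). Estimates that fail a peak-quality check return NA and are
# imputed downstream.

#' Pitch-estimation-filter fundamental
#'
#' Comb-filter-bank estimator: for every candidate fundamental on a grid,
#' the mean periodogram power at its harmonics up to Nyquist is scored; the
#' maximizing candidate (refined by parabolic interpolation over the grid)
#' is returned. The mean (rather than the sum) over harmonics penalizes
#' subharmonic candidates, whose extra comb teeth fall on noise. Segments
#' whose peak score does not stand out from the median score (ratio below
#' \code{minQualityPef}) are flagged missing.
#'
#' @param x real sample vector.
#' @param spec an [F0SearchSpec-class].
#' @param fs sampling rate.
#' @return estimated fundamental in Hz, or \code{NA} when flagged.
#' @export
estimateF0Pef <- function(x, spec = f0SearchSpec(), fs) {
  validObject(spec)
  if (stats::var(x) == 0) return(NA_real_)
  nfft <- 2^ceiling(log2(max(4 * length(x), 4096)))
  pg <- periodogramOneSided(x, fs, "hann", nfft = nfft)
  df <- fs / nfft
  grid <- seq(spec@fMin, spec@fMax, by = spec@gridHz)
  fTop <- 0.98 * fs / 2
  score <- vapply(grid, function(f0) {
    h <- seq_len(max(1, floor(fTop / f0)))
    mean(pg$power[round(h * f0 / df) + 1L])
  }, numeric(1))
  i <- which.max(score)
  if (score[i] <= 0 ||
      score[i] / stats::median(score) < spec@minQualityPef)
    return(NA_real_)
  iFrac <- parabolicPeak(score, i)
  clamp(spec@fMin + (iFrac - 1) * spec@gridHz, spec@fMin, spec@fMax)
}

#' Wavelet-transform fundamental
#'
#' Continuous Morlet wavelet transform ridge: the time-averaged squared
#' modulus of the CWT is computed on a frequency grid over the search range
#' (L2-normalized wavelets, FFT convolution) and the dominant scale is
#' mapped to Hz with parabolic refinement. Flat ridges (peak-to-median
#' energy ratio below \code{minQualityWt}) are flagged missing.
#'
#' @inheritParams estimateF0Pef
#' @return estimated fundamental in Hz, or \code{NA} when flagged.
#' @export
estimateF0Wavelet <- function(x, spec = f0SearchSpec(), fs) {
  validObject(spec)
  if (stats::var(x) == 0) return(NA_real_)
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  X <- fft(c(x - mean(x), rep(0, nfft - n)))
  omega <- 2 * pi * fs * (seq_len(nfft) - 1) / nfft
  pos <- omega < pi * fs            # analytic wavelet: positive freqs only
  grid <- seq(spec@fMin, spec@fMax, by = spec@gridHz)
  om0 <- spec@waveletOmega0
  energy <- vapply(grid, function(f) {
    s <- om0 / (2 * pi * f)
    H <- numeric(nfft)
    # unit-peak normalization: a pure tone gives the same ridge height at
    # every scale, so the ridge maximum sits exactly at the tone frequency
    H[pos] <- exp(-0.5 * (s * omega[pos] - om0)^2)
    w <- fft(X * H, inverse = TRUE) / nfft
    mean(Mod(w[seq_len(n)])^2)
  }, numeric(1))
  i <- which.max(energy)
  if (energy[i] <= 0 ||
      energy[i] / stats::median(energy) < spec@minQualityWt)
    return(NA_real_)
  iFrac <- parabolicPeak(energy, i)
  clamp(spec@fMin + (iFrac - 1) * spec@gridHz, spec@fMin, spec@fMax)
}

# FFT-based band-limited upsampling of a real sequence by integer factor U.
fftUpsample <- function(x, U) {
  n <- length(x)
  X <- fft(x)
  half <- floor(n / 2)
  Y <- complex(length.out = n * U)
  Y[seq_len(half + 1)] <- X[seq_len(half + 1)]
  if (half > 1)
    Y[(n * U - half + 2):(n * U)] <- X[(n - half + 2):n]
  if (n %% 2 == 0) {  # split the Nyquist bin symmetrically
    Y[half + 1] <- X[half + 1] / 2
    Y[n * U - half + 1] <- X[half + 1] / 2
  }
  Re(fft(Y, inverse = TRUE)) * U / (n * U)
}

#' Normalized-correlation-function fundamental
#'
#' Autocorrelation pitch: the fundamental lag maximizes the normalized
#' autocorrelation within \code{[fs/fMax, fs/fMin]}. Because fundamentals
#' near 300-400 Hz have periods of only a few samples at 1 kHz, the segment
#' is band-limited-upsampled (FFT zero padding, factor 8) before the lag
#' search so the correlation peak is densely sampled; the smallest of
#' near-equal peaks is taken (guarding against octave-down errors) and
#' refined by parabolic interpolation. Frames whose peak correlation is
#' below 0.3 are flagged missing.
#'
#' @inheritParams estimateF0Pef
#' @return estimated fundamental in Hz, or \code{NA} when flagged.
#' @export
estimateF0Ncf <- function(x, spec = f0SearchSpec(), fs) {
  validObject(spec)
  if (stats::var(x) == 0) return(NA_real_)
  U <- 8L
  xu <- fftUpsample(x, U)
  fsU <- fs * U
  L <- length(xu)
  lagMin <- max(2L, floor(fsU / spec@fMax))
  lagMax <- min(ceiling(fsU / spec@fMin), L - 2L)
  if (lagMax <= lagMin) return(NA_real_)
  psi <- normalizedAutocorrelation(xu, lagMax + 1L)
  rng <- lagMin:lagMax
  peak <- max(psi[rng])
  if (peak < 0.3) return(NA_real_)
  # smallest local maximum within 5% of the range maximum
  cand <- rng[psi[rng] >= 0.95 * peak]
  isLocalMax <- vapply(cand, function(k)
    psi[k] >= psi[k - 1L] && psi[k] >= psi[k + 1L], logical(1))
  k0 <- if (any(isLocalMax)) min(cand[isLocalMax]) else rng[which.max(psi[rng])]
  p <- parabolicPeak(psi, k0)
  clamp(fsU / p, spec@fMin, spec@fMax)
}
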