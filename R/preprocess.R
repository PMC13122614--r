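# Recording-level preprocessing: normalization, Chebyshev high-pass
# filtering and overlapping Hann framing.

#' Normalize a complex recording
#'
#' Removes the complex mean and scales to unit root-mean-square magnitude.
#' Normalization is per-recording so detection thresholds remain comparable
#' across the frames of one recording. An all-zero input is returned
#' unchanged; non-finite samples are rejected.
#'
#' @param iq complex (or real) sample vector.
#' @return complex vector with zero mean and unit RMS magnitude.
#' @export
normalizeIQ <- function(iq) {
  if (!length(iq)) stop("empty input")
  stopifnotFinite(iq, "iq")
  iq <- as.complex(iq)
  centred <- iq - mean(iq)
  rms <- sqrt(mean(Mod(centred)^2))
  if (rms == 0) return(iq)
  centred / rms
}

chebyCoefficients <- function(spec, fs) {
  validObject(spec)
  if (spec@cutoffHz >= fs / 2)
    stop("cutoff (", spec@cutoffHz, " Hz) must be below Nyquist (", fs / 2,
         " Hz)")
  signal::cheby1(spec@order, Rp = spec@rippleDb,
                 W = spec@cutoffHz / (fs / 2), type = "high")
}

#' High-pass filter a complex recording
#'
#' Applies the Chebyshev type-I high-pass of a [FilterSpec-class] to the
#' real and imaginary parts identically. The default mode is
#' forward-backward (zero phase), which squares the magnitude response and
#' preserves the harmonic phase relations consumed by the cepstral features.
#'
#' @param iq complex (or real) sample vector.
#' @param spec a [FilterSpec-class].
#' @param fs sampling rate (samples/s).
#' @return filtered vector (complex if the input was complex).
#' @export
highpassFilter <- function(iq, spec = filterSpec(), fs) {
  flt <- chebyCoefficients(spec, fs)
  apply1 <- function(x) {
    if (spec@mode == "forward-backward")
      signal::filtfilt(flt, x)
    else
      as.numeric(signal::filter(flt, x))
  }
  if (is.complex(iq)) {
    complex(real = apply1(Re(iq)), imaginary = apply1(Im(iq)))
  } else {
    apply1(iq)
  }
}

#' Reduce a complex signal to one real channel
#'
#' The harmonic-ratio statistic is defined for real sequences; this picks
#' the reduction applied to the filtered I/Q signal.
#'
#' @param iq complex vector.
#' @param channel \code{"real"}, \code{"imag"} or \code{"magnitude"}.
#' @return real vector.
#' @export
channelSignal <- function(iq, channel = c("real", "imag", "magnitude")) {
  channel <- match.arg(channel)
  switch(channel, real = Re(iq), imag = Im(iq), magnitude = Mod(iq))
}

#' Cut a signal into overlapping Hann-tapered frames
#'
#' Frames of \code{windowS} seconds with hop \code{windowS - overlapS};
#' frame \code{k} (0-based) starts at \code{k * hop} seconds. The frame
#' count is \code{floor((len/fs - windowS)/hop) + 1}; a recording shorter
#' than one window yields an empty result rather than an error.
#'
#' @param x real or complex sample vector.
#' @param spec a [FrameSpec-class].
#' @param fs sampling rate.
#' @param taper apply the Hann taper (TRUE for the detection statistic).
#' @return list with \code{frames} (list of vectors), \code{startS}
#'   (numeric) and \code{windowSamples}.
#' @export
frameSignal <- function(x, spec = frameSpec(), fs, taper = TRUE) {
  validObject(spec)
  L <- round(spec@windowS * fs)
  hop <- round((spec@windowS - spec@overlapS) * fs)
  if (hop < 1) stop("hop must span at least one sample")
  n <- length(x)
  if (n < L)
    return(list(frames = list(), startS = numeric(0), windowSamples = L))
  nFrames <- floor((n - L) / hop) + 1L
  w <- if (taper) hannWindow(L) else rep(1, L)
  starts <- (seq_len(nFrames) - 1L) * hop
  frames <- lapply(starts, function(s) x[(s + 1L):(s + L)] * w)
  list(frames = frames, startS = starts / fs, windowSamples = L)
}
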