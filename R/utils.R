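# Internal helpers shared across modules.

#' @importFrom stats rnorm runif fft sd median quantile
#' @importFrom methods new validObject is slot
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive `n` sub-seeds (< 2^31) from a master seed.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Symmetric Hann taper (endpoints exactly zero).
hannWindow <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

# One-sided periodogram of a real signal. Returns freq (Hz) and power.
# Power is |X_k|^2 summed over the one-sided bins; only relative shape and
# band fractions are consumed downstream, so no density scaling is applied.
periodogramOneSided <- function(x, fs, window = c("hann", "rect"), nfft = NULL) {
  window <- match.arg(window)
  n <- length(x)
  if (window == "hann") x <- x * hannWindow(n)
  if (is.null(nfft)) nfft <- n
  X <- fft(c(x, rep(0, nfft - n)))
  half <- floor(nfft / 2) + 1L
  p <- Mod(X[seq_len(half)])^2
  list(freq = (seq_len(half) - 1) * fs / nfft, power = p)
}

# Two-sided periodogram of a complex signal, frequencies in (-fs/2, fs/2].
periodogramComplex <- function(x, fs) {
  n <- length(x)
  X <- fft(x)
  p <- Mod(X)^2 / n
  f <- (seq_len(n) - 1) * fs / n
  f[f >= fs / 2] <- f[f >= fs / 2] - fs
  ord <- order(f)
  list(freq = f[ord], power = p[ord])
}

# Parabolic interpolation of a peak at index i of y; returns fractional index.
parabolicPeak <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(as.numeric(i))
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (!is.finite(denom) || denom == 0) return(as.numeric(i))
  i + 0.5 * (y[i - 1] - y[i + 1]) / denom
}

# Round a numeric matrix through IEEE single precision (round-trip via raw
# bytes), preserving dimensions.
roundToFloat32 <- function(m) {
  v <- readBin(writeBin(as.numeric(m), raw(), size = 4L), "numeric",
               n = length(m), size = 4L)
  array(v, dim = dim(m), dimnames = dimnames(m))
}

stopifnotFinite <- function(x, what = "input") {
  if (!all(is.finite(Re(x))) || (is.complex(x) && !all(is.finite(Im(x)))))
    stop(what, " contains non-finite samples")
  invisible(x)
}
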