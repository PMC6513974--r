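# Welch spectral estimation (internal): Hamming-windowed overlapping
# segments, averaged periodograms / cross-spectra. Segment length defaults
# to fs/2 samples with 50% overlap, the configuration used by the coherence
# similarity features.

.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

.welch_segments <- function(n, seg, overlap = 0.5) {
  step <- max(1L, round(seg * (1 - overlap)))
  starts <- seq(1L, n - seg + 1L, by = step)
  starts
}

# Returns list(freq, spec [, cross]) ; spec in power units (one-sided).
welch_psd <- function(x, fs, seg = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(seg)) seg <- max(8L, min(n, round(fs / 2)))
  seg <- min(seg, n)
  w <- .hamming(seg)
  starts <- .welch_segments(n, seg, overlap)
  half <- seq_len(floor(seg / 2) + 1L)
  acc <- numeric(length(half))
  for (s in starts) {
    xs <- x[s:(s + seg - 1L)]
    X <- stats::fft((xs - mean(xs)) * w)
    acc <- acc + Mod(X[half])^2
  }
  scale <- sum(w^2) * length(starts)
  spec <- acc / scale
  # one-sided: double interior bins
  if (length(half) > 2) spec[2:(length(half) - 1L)] <- 2 * spec[2:(length(half) - 1L)]
  list(freq = (half - 1) * fs / seg, spec = spec)
}

# Magnitude-squared coherence between x and y (equal length).
welch_coherence <- function(x, y, fs, seg = NULL, overlap = 0.5) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(seg)) seg <- max(8L, min(n, round(fs / 2)))
  seg <- min(seg, n)
  w <- .hamming(seg)
  starts <- .welch_segments(n, seg, overlap)
  half <- seq_len(floor(seg / 2) + 1L)
  sxx <- syy <- numeric(length(half))
  sxy <- complex(length(half))
  for (s in starts) {
    xs <- x[s:(s + seg - 1L)]; ys <- y[s:(s + seg - 1L)]
    X <- stats::fft((xs - mean(xs)) * w)[half]
    Y <- stats::fft((ys - mean(ys)) * w)[half]
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  denom <- sxx * syy
  coh <- ifelse(denom > 0, Mod(sxy)^2 / denom, 0)
  list(freq = (half - 1) * fs / seg, coherence = as.numeric(coh),
       n_segments = length(starts))
}
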