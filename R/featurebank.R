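#' Feature extraction configuration
#'
#' Tunable parameters of the feature bank: embedding dimension `m` and
#' tolerance fraction `r_frac` (times the signal SD) for the template
#' entropies, histogram bin count for Shannon entropy and mutual
#' information, sub-window count for the segment-based stationarity
#' features, maximum lag for the lag-dependence features, and the coherence
#' summary bands per modality (EMG: the EMG passband; SCL: 0--2 Hz).
#'
#' @param m Template length (default 2).
#' @param r_frac Tolerance as a fraction of SD (default 0.2).
#' @param n_bins Histogram bins (default 16).
#' @param n_segments Sub-windows for SDMN/SDSD (default 10).
#' @param max_lag Maximum lag for LDF/PLDF (default 32).
#' @param scl_band Coherence summary band for SCL, Hz.
#' @param pre Preprocessing settings, see [preprocess_config()].
#' @return Named list of settings.
#' @export
feature_config <- function(m = 2, r_frac = 0.2, n_bins = 16, n_segments = 10,
                           max_lag = 32, scl_band = c(0, 2),
                           pre = preprocess_config()) {
  list(m = m, r_frac = r_frac, n_bins = n_bins, n_segments = n_segments,
       max_lag = max_lag, scl_band = scl_band, pre = pre)
}

# local extrema by strict sign change of the first difference
.local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  d1 <- diff(x)
  dl <- d1[-(n - 1)]
  dr <- d1[-1]
  i <- 2:(n - 1)
  list(max = i[dl > 0 & dr < 0], min = i[dl < 0 & dr > 0])
}

#' Amplitude features
#'
#' MAV, RMS, PK (peak magnitude), P2P (peak-to-peak), first and second
#' higher-order MAVs (MAV of the first/second difference) with their
#' MAV-normalized variants, and the mean relative times of the local maxima
#' (TMNP) and minima (TMNV) as fractions of the window (0 when the signal
#' has no extrema).
#'
#' @param x Numeric signal (length >= 3).
#' @return Named numeric vector of 10 features.
#' @export
amplitude_features <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples")
  mav <- mean(abs(x))
  homav1 <- mean(abs(diff(x)))
  homav2 <- mean(abs(diff(x, differences = 2)))
  nrm <- function(v) if (mav > 0) v / mav else 0
  ext <- .local_extrema(x)
  reltime <- function(idx) if (length(idx)) mean((idx - 1) / (n - 1)) else 0
  c(MAV = mav, RMS = sqrt(mean(x^2)), PK = max(abs(x)),
    P2P = max(x) - min(x),
    HOMAV1 = homav1, HOMAV1n = nrm(homav1),
    HOMAV2 = homav2, HOMAV2n = nrm(homav2),
    TMNP = reltime(ext$max), TMNV = reltime(ext$min))
}

#' Variability features
#'
#' Sample variance and SD (n-1 denominators), range, and interquartile range
#' with linear-interpolation quantiles.
#'
#' @param x Numeric signal (length >= 2).
#' @return Named numeric vector `VAR`, `SD`, `R`, `IQR`.
#' @export
variability_features <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  c(VAR = stats::var(x), SD = stats::sd(x), R = max(x) - min(x),
    IQR = q[2] - q[1])
}

#' Stationarity features
#'
#' Median (MD); SD of sub-window means (SDMN) and of sub-window SDs (SDSD)
#' over `n_segments` equal non-overlapping sub-windows; and the
#' degree-of-stationarity family from the Hilbert spectrum
#' `H(freq, time)`: `DS(f) = mean_t (1 - H(f,t)/Hbar(f))^2`, with IDS its
#' integral over frequency (trapezoid, Hz), and the "modified" variants
#' weighting DS by the marginal spectral energy (MIDS: weighted integral;
#' MMNDS: weighted mean).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param n_segments Sub-window count (default 10).
#' @param hs Hilbert spectrum of `x`, see [hilbert_spectrum()].
#' @return Named numeric vector `MD`, `SDMN`, `SDSD`, `MMNDS`, `IDS`, `MIDS`.
#' @export
stationarity_features <- function(x, fs, n_segments = 10, hs = NULL) {
  n <- length(x)
  if (n_segments < 2) stop("n_segments must be >= 2")
  if (n_segments > n) stop("n_segments exceeds signal length")
  if (is.null(hs)) hs <- hilbert_spectrum(x, fs)
  seg_len <- n %/% n_segments
  segs <- matrix(x[seq_len(seg_len * n_segments)], seg_len, n_segments)
  mns <- colMeans(segs)
  sds <- apply(segs, 2, stats::sd)

  H <- hs$energy  # time x freq
  hbar <- colMeans(H)
  ds <- numeric(length(hbar))
  nz <- hbar > 0
  if (any(nz))
    ds[nz] <- colMeans((1 - sweep(H[, nz, drop = FALSE], 2, hbar[nz], "/"))^2)
  etot <- sum(H)
  w <- if (etot > 0) colSums(H) / etot else rep(0, length(hbar))
  trapz <- function(f, y) if (length(f) > 1) sum(diff(f) * (y[-1] + y[-length(y)]) / 2) else 0
  ids <- trapz(hs$freq, ds)
  mids <- trapz(hs$freq, ds * w)
  mmnds <- if (sum(w) > 0) sum(ds * w) / sum(w) else 0
  c(MD = stats::median(x), SDMN = stats::sd(mns), SDSD = stats::sd(sds),
    MMNDS = mmnds, IDS = ids, MIDS = mids)
}

#' Entropy features
#'
#' Approximate, sample, and fuzzy entropy (Chebyshev distance, tolerance
#' `r = r_frac * SD(x)`, exponential membership `exp(-(d/r)^2)` for fuzzy
#' entropy); Shannon entropy of an `n_bins` amplitude histogram (bits); and
#' spectral entropy (Shannon entropy of the normalized Welch power spectrum
#' divided by `log2` of the number of spectral bins, in [0, 1]). A constant
#' signal yields all zeros by convention.
#'
#' @param x Numeric signal (length >= 50 for meaningful template entropies).
#' @param m Template length (default 2).
#' @param r_frac Tolerance fraction of SD (default 0.2).
#' @param n_bins Histogram bins (default 16).
#' @param fs Sampling rate, used for the spectral estimate (default 1:
#'   entropy is scale-free in frequency).
#' @param psd Optional pre-computed Welch spectrum of `x` (internal reuse).
#' @return Named numeric vector `ApEn`, `SampEn`, `FuzzyEn`, `ShannonEn`,
#'   `SpectralEn`.
#' @export
entropy_features <- function(x, m = 2, r_frac = 0.2, n_bins = 16, fs = 1,
                             psd = NULL) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    return(c(ApEn = 0, SampEn = 0, FuzzyEn = 0, ShannonEn = 0, SpectralEn = 0))
  r <- r_frac * s
  brk <- seq(min(x), max(x), length.out = n_bins + 1L)
  cnt <- tabulate(findInterval(x, brk, rightmost.closed = TRUE,
                               all.inside = TRUE), n_bins)
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  shannon <- -sum(p * log2(p))
  ps <- if (is.null(psd)) welch_psd(x, fs) else psd
  spec <- ps$spec
  spectral <- 0
  if (sum(spec) > 0) {
    q <- spec / sum(spec)
    q <- q[q > 0]
    spectral <- -sum(q * log2(q)) / log2(length(spec))
  }
  c(ApEn = .apen_cpp(x, as.integer(m), r),
    SampEn = .sampen_cpp(x, as.integer(m), r),
    FuzzyEn = .fuzzyen_cpp(x, as.integer(m), r),
    ShannonEn = shannon, SpectralEn = spectral)
}

# histogram mutual information between paired samples, in nats;
# miller_madow applies the standard positive-bias correction
.hist_mi <- function(a, b, n_bins = 16, miller_madow = FALSE) {
  n <- length(a)
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2]) return(0)
  ba <- pmin(floor((a - ra[1]) / (ra[2] - ra[1]) * n_bins) + 1L, n_bins)
  bb <- pmin(floor((b - rb[1]) / (rb[2] - rb[1]) * n_bins) + 1L, n_bins)
  joint <- tabulate((ba - 1L) * n_bins + bb, n_bins * n_bins) / n
  pa <- tabulate(ba, n_bins) / n
  pb <- tabulate(bb, n_bins) / n
  nzj <- joint > 0
  mi <- sum(joint[nzj] * log(joint[nzj])) -
    sum(pa[pa > 0] * log(pa[pa > 0])) - sum(pb[pb > 0] * log(pb[pb > 0]))
  if (miller_madow) {
    kj <- sum(nzj); ka <- sum(pa > 0); kb <- sum(pb > 0)
    mi <- mi - (kj - ka - kb + 1) / (2 * n)
  }
  max(mi, 0)
}

# MI (nats) between two pre-binned index vectors, Miller-Madow corrected
.binned_mi <- function(ba, bb, n_bins, miller_madow = TRUE) {
  n <- length(ba)
  joint <- tabulate((ba - 1L) * n_bins + bb, n_bins * n_bins) / n
  pa <- tabulate(ba, n_bins) / n
  pb <- tabulate(bb, n_bins) / n
  nzj <- joint > 0
  mi <- sum(joint[nzj] * log(joint[nzj])) -
    sum(pa[pa > 0] * log(pa[pa > 0])) - sum(pb[pb > 0] * log(pb[pb > 0]))
  if (miller_madow)
    mi <- mi - (sum(nzj) - sum(pa > 0) - sum(pb > 0) + 1) / (2 * n)
  max(mi, 0)
}

#' Linearity (lag dependence) features
#'
#' For each lag `tau` in `1..max_lag`, linear dependence is the squared
#' autocorrelation `rho(tau)^2` and total dependence is the
#' mutual-information-derived coefficient `g(tau) = 1 - exp(-2 MI(tau))`
#' (histogram MI over a fixed amplitude binning of the series, Miller-Madow
#' bias corrected). The excess nonlinear dependence `max(0, g - rho^2)` is
#' averaged over lags (LDF); PLDF computes the same statistic on the pooled
#' lag-pair population.
#'
#' @param x Numeric signal.
#' @param max_lag Maximum lag (default 32; must be below `length(x)/4`).
#' @param n_bins Histogram bins for the MI estimate.
#' @return Named numeric vector `LDF`, `PLDF`.
#' @export
linearity_features <- function(x, max_lag = 32, n_bins = 16) {
  n <- length(x)
  if (max_lag >= n / 4) stop("max_lag must be below length(x)/4")
  r <- range(x)
  if (r[1] == r[2]) return(c(LDF = 0, PLDF = 0))
  bx <- pmin(floor((x - r[1]) / (r[2] - r[1]) * n_bins) + 1L, n_bins)
  rho <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                               demean = TRUE)$acf)[-1]
  rho[!is.finite(rho)] <- 0
  excess <- numeric(max_lag)
  for (tau in seq_len(max_lag)) {
    ba <- bx[seq_len(n - tau)]
    bb <- bx[(tau + 1):n]
    g <- 1 - exp(-2 * .binned_mi(ba, bb, n_bins))
    excess[tau] <- max(0, g - rho[tau]^2)
  }
  ia <- unlist(lapply(seq_len(max_lag), function(tau) seq_len(n - tau)))
  ib <- unlist(lapply(seq_len(max_lag), function(tau) (tau + 1):n))
  rho2p <- suppressWarnings(stats::cor(x[ia], x[ib])^2)
  if (!is.finite(rho2p)) rho2p <- 0
  gp <- 1 - exp(-2 * .binned_mi(bx[ia], bx[ib], n_bins))
  c(LDF = mean(excess), PLDF = max(0, gp - rho2p))
}

#' Similarity features
#'
#' Similarity of a measurement window to the subject's pain-free baseline
#' recording of the same channel: Pearson correlation (CC), histogram mutual
#' information (MI, 16 x 16 bins, nats), and summaries of the Welch
#' magnitude-squared coherence over the modality passband — mean (MNCOH),
#' median (MDCOH), trapezoid integral over Hz (MICOH), and the mean
#' restricted to bins with coherence above 0.5 (MMNCOH; 0 when empty).
#'
#' @param x Numeric signal.
#' @param ref Baseline reference signal, equal length and sampling rate.
#' @param fs Sampling rate (Hz).
#' @param band Passband in Hz for the coherence summaries.
#' @param n_bins MI histogram bins.
#' @return Named numeric vector `CC`, `MI`, `MNCOH`, `MDCOH`, `MICOH`,
#'   `MMNCOH`.
#' @export
similarity_features <- function(x, ref, fs, band = c(0, fs / 2), n_bins = 16) {
  if (length(x) != length(ref)) stop("x and ref must have equal length")
  cc <- suppressWarnings(stats::cor(x, ref))
  if (!is.finite(cc)) cc <- 0
  mi <- .hist_mi(x, ref, n_bins)
  co <- welch_coherence(x, ref, fs)
  inb <- co$freq >= band[1] & co$freq <= band[2]
  f <- co$freq[inb]; coh <- co$coherence[inb]
  if (!length(coh)) { f <- co$freq; coh <- co$coherence }
  hi <- coh > 0.5
  trapz <- function(f, y) if (length(f) > 1) sum(diff(f) * (y[-1] + y[-length(y)]) / 2) else 0
  c(CC = cc, MI = mi, MNCOH = mean(coh), MDCOH = stats::median(coh),
    MICOH = trapz(f, coh), MMNCOH = if (any(hi)) mean(coh[hi]) else 0)
}

#' Frequency features
#'
#' From the Welch power spectrum `P(f)`: mean frequency (MNF), interpolated
#' median frequency (MDF), mode frequency (MOF, the spectral peak), spectral
#' bandwidth around MNF (BW), center (RMS) frequency (CF), and the count of
#' sign changes of the signal (ZC, zero-amplitude samples skipped). An
#' all-zero signal yields all zeros.
#'
#' @param x Numeric signal (length >= 64).
#' @param fs Sampling rate (Hz).
#' @param psd Optional pre-computed Welch spectrum of `x` (internal reuse).
#' @return Named numeric vector `MNF`, `MDF`, `MOF`, `BW`, `CF`, `ZC`.
#' @export
frequency_features <- function(x, fs, psd = NULL) {
  if (length(x) < 64) stop("need at least 64 samples")
  zc <- {
    s <- sign(x)
    s <- s[s != 0]
    if (length(s) > 1) sum(diff(s) != 0) else 0
  }
  ps <- if (is.null(psd)) welch_psd(x, fs) else psd
  P <- ps$spec; f <- ps$freq
  tot <- sum(P)
  if (tot == 0)
    return(c(MNF = 0, MDF = 0, MOF = 0, BW = 0, CF = 0, ZC = zc))
  mnf <- sum(f * P) / tot
  cum <- cumsum(P)
  half <- tot / 2
  i <- which(cum >= half)[1]
  mdf <- if (i == 1) f[1] else {
    f[i - 1] + (half - cum[i - 1]) / (cum[i] - cum[i - 1]) * (f[i] - f[i - 1])
  }
  c(MNF = mnf, MDF = mdf, MOF = f[which.max(P)],
    BW = sqrt(sum((f - mnf)^2 * P) / tot), CF = sqrt(sum(f^2 * P) / tot),
    ZC = zc)
}

#' Heart-rate-variability features
#'
#' Detects R peaks by bandpass filtering (5--30 Hz), squaring, and an
#' adaptive threshold (0.5 times the rolling maximum over a 1.5 s window)
#' with a 250 ms refractory period, then computes RR intervals in ms: mean
#' interval (MNRR), root mean square of successive differences (RMSSD), and
#' the least-squares slope of RR against beat index (slopeRR, ms/beat).
#' Windows with fewer than 3 detected peaks yield zeros with attribute
#' `hrv_sparse = TRUE`.
#'
#' @param ecg Numeric ECG signal.
#' @param fs Sampling rate (Hz).
#' @return Named numeric vector `MNRR`, `RMSSD`, `slopeRR`.
#' @export
hrv_features <- function(ecg, fs) {
  peaks <- detect_r_peaks(ecg, fs)
  if (length(peaks) < 3) {
    out <- c(MNRR = 0, RMSSD = 0, slopeRR = 0)
    attr(out, "hrv_sparse") <- TRUE
    return(out)
  }
  rr <- diff(peaks) / fs * 1000
  idx <- seq_along(rr)
  slope <- if (length(rr) > 1) stats::cov(idx, rr) / stats::var(idx) else 0
  c(MNRR = mean(rr),
    RMSSD = if (length(rr) > 1) sqrt(mean(diff(rr)^2)) else 0,
    slopeRR = slope)
}

#' Detect R peaks
#'
#' @param ecg Numeric ECG signal.
#' @param fs Sampling rate (Hz).
#' @param refractory Minimum peak spacing in seconds (default 0.25).
#' @return Integer sample indices of detected R peaks.
#' @export
detect_r_peaks <- function(ecg, fs, refractory = 0.25) {
  hi <- min(30, 0.45 * fs)
  y <- bandpass_filter(ecg, fs, 5, hi)^2
  w <- max(3L, round(1.5 * fs))
  thr <- 0.5 * .rolling_max(y, w)
  ext <- .local_extrema(y)
  cand <- ext$max[y[ext$max] >= thr[ext$max]]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(y[cand], decreasing = TRUE)]
  gap <- round(refractory * fs)
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) > gap)) keep <- c(keep, i)
  }
  sort(keep)
}

# centered rolling maximum in O(n) (two-pass block cummax), edges padded
.rolling_max <- function(x, w) {
  n <- length(x)
  half <- w %/% 2
  p <- c(rep(x[1], half), x, rep(x[n], w - half - 1L))
  np <- length(p)
  pad_to <- ceiling(np / w) * w
  p2 <- c(p, rep(p[np], pad_to - np))
  m <- matrix(p2, nrow = w)
  left <- as.numeric(apply(m, 2, cummax))
  right <- as.numeric(apply(m[w:1, , drop = FALSE], 2, cummax)[w:1, , drop = FALSE])
  i <- seq_len(n)
  pmax(right[i], left[i + w - 1L])
}
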