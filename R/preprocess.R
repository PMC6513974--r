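#' Zero-phase Butterworth bandpass filter
#'
#' Designs a Butterworth filter of the given order and applies it forward and
#' backward (zero phase), so peak timings used by downstream features are not
#' shifted. A `low` of 0 designs a lowpass.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param low,high Band edges in Hz; `0 <= low < high < fs/2`.
#' @param order Filter order (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low, high, order = 4) {
  if (low < 0 || low >= high || high >= fs / 2)
    stop("band [", low, ", ", high, "] Hz outside (0, Nyquist = ", fs / 2, ")")
  if (order < 1) stop("order must be >= 1")
  bf <- if (low == 0)
    signal::butter(order, high / (fs / 2), type = "low")
  else
    signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  .zp_filter(bf, x)
}

# zero-phase IIR filtering with odd-reflection padding and steady-state
# initial conditions (so edge transients do not leak into the window)
.zp_filter <- function(bf, x) {
  b <- bf$b; a <- bf$a
  n <- length(x)
  p <- min(3L * (max(length(b), length(a)) - 1L), n - 1L)
  ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  h0 <- sum(b) / sum(a)
  pass <- function(z) {
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1], length(b) - 1L),
                              init.y = rep(z[1] * h0, length(a) - 1L)))
  }
  y <- rev(pass(rev(pass(ext))))
  y[(p + 1):(p + n)]
}

#' Empirical mode decomposition
#'
#' Standard EMD by sifting with natural-cubic-spline extrema envelopes and a
#' Cauchy-type stopping criterion.
#'
#' @param x Numeric signal.
#' @param max_imf Maximum number of intrinsic mode functions (default 10).
#' @param tol Sifting stop tolerance (default 0.2).
#' @param max_sift Maximum sifting iterations per IMF (default 50).
#' @return List with `imf` (matrix, one column per IMF; zero columns for a
#'   signal without oscillations) and `residual`.
#' @export
emd <- function(x, max_imf = 10, tol = 0.2, max_sift = 50) {
  res <- .emd_cpp(as.numeric(x), as.integer(max_imf), tol, as.integer(max_sift))
  if (!all(is.finite(res$residual)) ||
      (ncol(res$imf) > 0 && !all(is.finite(res$imf))))
    stop("EMD failed to converge (non-finite sift output)")
  res
}

# dominant frequency (Hz) of each IMF column via FFT peak
.imf_peak_freq <- function(imf, fs) {
  n <- nrow(imf)
  if (ncol(imf) == 0) return(numeric(0))
  sp <- Mod(stats::mvfft(imf))^2
  half <- seq_len(floor(n / 2))
  freqs <- (half - 1) * fs / n
  apply(sp[half, , drop = FALSE], 2, function(p) freqs[which.max(p)])
}

#' Remove power-line interference via EMD
#'
#' Decomposes the signal into intrinsic mode functions, finds the IMF whose
#' dominant (FFT-peak) frequency is nearest `line_freq` and within
#' `tol_hz` of it, and reconstructs the signal without that IMF. If no IMF
#' qualifies the input is returned unchanged, with attribute
#' `powerline_removed = FALSE`.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param line_freq Power-line frequency (default 50 Hz); must be below
#'   Nyquist.
#' @param tol_hz Matching tolerance band (default 5 Hz).
#' @param decomposition Optional pre-computed [emd()] result for `x` (reused
#'   by the pipeline to avoid decomposing twice).
#' @return Cleaned signal with attribute `powerline_removed` (logical) and,
#'   when removed, `line_imf` (the index of the dropped IMF).
#' @export
remove_powerline <- function(x, fs, line_freq = 50, tol_hz = 5,
                             decomposition = NULL) {
  if (line_freq >= fs / 2) stop("line_freq must be below Nyquist")
  dec <- if (is.null(decomposition)) emd(x) else decomposition
  pk <- .imf_peak_freq(dec$imf, fs)
  if (length(pk) == 0) {
    out <- as.numeric(x)
    attr(out, "powerline_removed") <- FALSE
    return(out)
  }
  dist <- abs(pk - line_freq)
  best <- which.min(dist)
  if (dist[best] > tol_hz) {
    out <- as.numeric(x)
    attr(out, "powerline_removed") <- FALSE
    return(out)
  }
  out <- as.numeric(x) - dec$imf[, best]
  attr(out, "powerline_removed") <- TRUE
  attr(out, "line_imf") <- best
  out
}

#' Extract the response window
#'
#' Pure half-open slice `[onset, onset + duration)` of a sampled signal.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param onset Window start in seconds (>= 0).
#' @param duration Window length in seconds.
#' @return `round(duration * fs)` samples starting at `onset`.
#' @export
response_window <- function(x, fs, onset, duration) {
  if (onset < 0) stop("onset must be >= 0")
  start <- round(onset * fs)
  len <- round(duration * fs)
  if (start + len > length(x))
    stop("window [", onset, ", ", onset + duration, ") s exceeds the recording")
  x[(start + 1):(start + len)]
}

# analytic signal via FFT (one-sided spectrum doubling)
.analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert spectrum
#'
#' Time-frequency energy distribution built from the analytic signals of the
#' intrinsic mode functions: per IMF, instantaneous amplitude and frequency;
#' squared amplitudes are accumulated over a (time, frequency) grid. Total
#' energy equals the sum of squared IMF amplitudes by construction
#' (out-of-range instantaneous frequencies are clamped to the grid).
#'
#' @param x Numeric signal (length >= 64).
#' @param fs Sampling rate (Hz).
#' @param n_freq_bins Number of frequency bins spanning `[0, fs/2]`
#'   (default 64).
#' @param time_decim Samples per time bin (default 16).
#' @param decomposition Optional pre-computed [emd()] result for `x`.
#' @return Object of class `pf_hspec`: list with `time` (bin centers, s),
#'   `freq` (bin centers, Hz), `energy` (time x frequency matrix, >= 0).
#' @export
hilbert_spectrum <- function(x, fs, n_freq_bins = 64, time_decim = 16,
                             decomposition = NULL) {
  n <- length(x)
  if (n < 64) stop("signal too short for a Hilbert spectrum (need >= 64 samples)")
  dec <- if (is.null(decomposition)) emd(x) else decomposition
  n_time <- ceiling(n / time_decim)
  energy <- matrix(0, n_time, n_freq_bins)
  tbin <- pmin(((seq_len(n) - 1) %/% time_decim) + 1L, n_time)
  if (ncol(dec$imf) > 0) {
    idx_all <- amp2_all <- vector("list", ncol(dec$imf))
    for (j in seq_len(ncol(dec$imf))) {
      a <- .analytic(dec$imf[, j])
      amp2 <- Mod(a)^2
      ph <- Arg(a)
      inst <- c(diff(ph), 0)
      inst <- (inst + pi) %% (2 * pi) - pi  # unwrap steps to (-pi, pi]
      instf <- abs(inst) * fs / (2 * pi)
      fbin <- pmin(pmax(floor(instf / (fs / 2) * n_freq_bins) + 1L, 1L),
                   n_freq_bins)
      idx_all[[j]] <- tbin + (fbin - 1L) * n_time
      amp2_all[[j]] <- amp2
    }
    idx <- unlist(idx_all)
    ui <- sort(unique(idx))
    energy[ui] <- energy[ui] + rowsum(unlist(amp2_all), idx)
  }
  structure(list(
    time = (seq_len(n_time) - 0.5) * time_decim / fs,
    freq = (seq_len(n_freq_bins) - 0.5) * (fs / 2) / n_freq_bins,
    energy = energy
  ), class = "pf_hspec")
}

#' Default preprocessing configuration
#'
#' Band edges and EMD settings used by [preprocess_trial()]. EMG channels
#' are bandpass filtered (default 20--250 Hz), ECG 0.1--250 Hz; the SCL
#' channel is only segmented, not filtered. Upper edges are capped just
#' below Nyquist when the sampling rate is reduced.
#'
#' @param emg_band,ecg_band Filter bands in Hz.
#' @param line_freq Power-line frequency for EMD removal (NA disables).
#' @param n_freq_bins,time_decim Hilbert spectrum grid.
#' @return Named list of settings.
#' @export
preprocess_config <- function(emg_band = c(20, 250), ecg_band = c(0.1, 250),
                              line_freq = 50, n_freq_bins = 64,
                              time_decim = 16) {
  list(emg_band = emg_band, ecg_band = ecg_band, line_freq = line_freq,
       n_freq_bins = n_freq_bins, time_decim = time_decim)
}

.cap_band <- function(band, fs) c(band[1], min(band[2], 0.45 * fs))

#' Preprocess one trial
#'
#' Applies, per channel: bandpass filtering (EMG and ECG only), EMD-based
#' power-line removal, response-window segmentation, and computes the Hilbert
#' spectrum of each continuous channel (from the same decomposition, with the
#' power-line IMF excluded). Each cleaned channel carries a `provenance`
#' attribute listing the applied steps.
#'
#' @param trial A `pf_trial`.
#' @param config See [preprocess_config()].
#' @param imf_dir Optional directory: when given, each channel's intrinsic
#'   mode functions are dumped to `<trial_id>_<channel>_imfs.csv` for
#'   inspection.
#' @return List with `channels` (named list of cleaned windows), `hspec`
#'   (named list of `pf_hspec` for zEMG/cEMG/tEMG/SCL), `fs`, and the trial
#'   metadata.
#' @export
preprocess_trial <- function(trial, config = preprocess_config(),
                             imf_dir = NULL) {
  stopifnot(inherits(trial, "pf_trial"))
  fs <- trial$fs
  emg_band <- .cap_band(config$emg_band, fs)
  ecg_band <- .cap_band(config$ecg_band, fs)
  out <- list()
  hspec <- list()
  for (ch in names(trial$channels)) {
    x <- trial$channels[[ch]]
    prov <- character(0)
    if (ch %in% c("zEMG", "cEMG", "tEMG")) {
      x <- bandpass_filter(x, fs, emg_band[1], emg_band[2])
      prov <- c(prov, sprintf("bandpass[%g-%g]", emg_band[1], emg_band[2]))
    } else if (ch == "ECG") {
      x <- bandpass_filter(x, fs, ecg_band[1], ecg_band[2])
      prov <- c(prov, sprintf("bandpass[%g-%g]", ecg_band[1], ecg_band[2]))
    }
    dec <- NULL
    if (!is.na(config$line_freq)) {
      dec <- emd(x)
      if (!is.null(imf_dir)) {
        dir.create(imf_dir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(
          as.data.frame(cbind(dec$imf, residual = dec$residual)),
          file.path(imf_dir, sprintf("%s_%s_imfs.csv", trial$trial_id, ch)),
          row.names = FALSE)
      }
      x2 <- remove_powerline(x, fs, config$line_freq, decomposition = dec)
      if (isTRUE(attr(x2, "powerline_removed"))) {
        keep <- setdiff(seq_len(ncol(dec$imf)), attr(x2, "line_imf"))
        dec <- list(imf = dec$imf[, keep, drop = FALSE], residual = dec$residual)
        prov <- c(prov, sprintf("emd_line_removal[%g]", config$line_freq))
      }
      x <- as.numeric(x2)
    }
    x <- response_window(x, fs, trial$stimulus_onset, 5.5)
    prov <- c(prov, "window[5.5s]")
    if (ch != "ECG") {
      dec_w <- if (!is.null(dec))
        list(imf = dec$imf[seq_along(x), , drop = FALSE],
             residual = dec$residual[seq_along(x)])
      else NULL
      hspec[[ch]] <- hilbert_spectrum(x, fs, config$n_freq_bins,
                                      config$time_decim, decomposition = dec_w)
    }
    attr(x, "provenance") <- prov
    attr(x, "modality") <- ch
    out[[ch]] <- x
  }
  list(channels = out, hspec = hspec, fs = fs,
       subject_id = trial$subject_id, trial_id = trial$trial_id,
       level = trial$level)
}
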