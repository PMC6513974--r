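test_that("amplitude features match hand-computed values", {
  f <- amplitude_features(c(1, -1, 2, -2))
  expect_equal(unname(f["MAV"]), 1.5)
  expect_equal(unname(f["PK"]), 2)
  expect_equal(unname(f["P2P"]), 4)
  expect_equal(unname(f["HOMAV1"]), 3)
  expect_equal(unname(f["HOMAV1n"]), 2)
  expect_equal(unname(f["TMNV"]), 1 / 3)
  expect_equal(unname(f["TMNP"]), 2 / 3)

  g <- amplitude_features(rep(3, 100))
  expect_equal(unname(g[c("MAV", "RMS", "P2P", "TMNP", "TMNV")]),
               c(3, 3, 0, 0, 0))
  expect_error(amplitude_features(c(1, 2)), "3 samples")
})

test_that("variability features match hand-computed values", {
  f <- variability_features(c(0, 2, 4))
  expect_equal(unname(f[c("VAR", "SD", "R")]), c(4, 2, 4))
  expect_equal(unname(variability_features(rep(5, 10))), rep(0, 4))
  expect_error(variability_features(3), "2 samples")
})

test_that("segment stationarity features detect a mean shift", {
  expect_equal(unname(stationarity_features(rep(2, 512), 64)[c("SDMN", "SDSD")]),
               c(0, 0))
  set.seed(10)
  x <- c(rnorm(500), rnorm(500) + 5)
  f <- stationarity_features(x, 100, n_segments = 2)
  expect_gt(f[["SDMN"]], 3)
  expect_equal(f[["MD"]], median(x))
  expect_error(stationarity_features(rnorm(100), 10, n_segments = 200),
               "exceeds")
})

test_that("amplitude-modulated noise has larger IDS than stationary noise", {
  set.seed(11)
  n <- 512
  wins <- 0
  for (i in 1:60) {
    flat <- rnorm(n)
    ramp <- rnorm(n) * seq(0.2, 1.8, length.out = n)
    ids_flat <- stationarity_features(flat, 128)[["IDS"]]
    ids_ramp <- stationarity_features(ramp, 128)[["IDS"]]
    wins <- wins + (ids_ramp > ids_flat)
  }
  expect_gte(wins / 60, 0.95)
})

test_that("entropy features honor degenerate conventions and bin counts", {
  expect_equal(unname(entropy_features(rep(1, 200))), rep(0, 5))
  x <- rep(c(0, 1), 250)
  expect_equal(entropy_features(x, n_bins = 2)[["ShannonEn"]], 1)
  set.seed(12)
  r <- entropy_features(rnorm(300), fs = 100)
  expect_true(all(is.finite(r)))
  expect_gt(r[["SampEn"]], 0)
})

test_that("sample entropy matches the brute-force template-counting oracle", {
  set.seed(13)
  x <- rnorm(500)
  r <- 0.2 * sd(x)
  expect_equal(entropy_features(x)[["SampEn"]], oracle_sampen(x, 2, r),
               tolerance = 1e-9)
})

test_that("linearity features separate linear from nonlinear dynamics", {
  set.seed(14)
  n <- 2000
  # AR(1): purely linear dependence leaves little excess
  below <- 0
  for (i in 1:40) {
    x <- as.numeric(arima.sim(list(ar = 0.8), n))
    if (linearity_features(x)[["LDF"]] < 0.05) below <- below + 1
  }
  expect_gte(below / 40, 0.9)
  # logistic map beats white noise in excess dependence
  wins <- 0
  for (i in 1:40) {
    x <- numeric(n); x[1] <- runif(1, 0.1, 0.9)
    for (t in 2:n) x[t] <- 4 * x[t - 1] * (1 - x[t - 1])
    w <- rnorm(n)
    if (linearity_features(x)[["LDF"]] > linearity_features(w)[["LDF"]])
      wins <- wins + 1
  }
  expect_gte(wins / 40, 0.95)
  # white noise pooled statistic near zero
  set.seed(15)
  expect_lt(linearity_features(rnorm(n))[["PLDF"]], 0.02)
  expect_error(linearity_features(rnorm(100), max_lag = 50), "max_lag")
})

test_that("similarity features are exact for self-comparison and near zero for noise", {
  set.seed(16)
  x <- rnorm(1408)
  f <- similarity_features(x, x, fs = 128)
  expect_equal(f[["CC"]], 1)
  expect_equal(f[["MNCOH"]], 1, tolerance = 1e-9)
  expect_equal(f[["MDCOH"]], 1, tolerance = 1e-9)

  y <- rnorm(2816); z <- rnorm(2816)
  expect_lt(abs(similarity_features(y, z, fs = 512)[["CC"]]), 0.1)
  expect_error(similarity_features(y, z[-1], fs = 512), "equal length")
})

test_that("coherence summaries match the brute-force Welch oracle", {
  set.seed(17)
  fs <- 64
  x <- rnorm(512)
  y <- x + rnorm(512)  # 0 dB SNR
  f <- similarity_features(x, y, fs = fs, band = c(0, fs / 2))
  o <- oracle_coherence(x, y, fs)
  expect_equal(f[["MNCOH"]], mean(o$coherence), tolerance = 1e-9)
  expect_equal(f[["MDCOH"]], median(o$coherence), tolerance = 1e-9)
  hi <- o$coherence > 0.5
  expect_equal(f[["MMNCOH"]], if (any(hi)) mean(o$coherence[hi]) else 0,
               tolerance = 1e-9)
})

test_that("frequency features localize a pure tone and count crossings", {
  fs <- 1000
  t <- (0:999) / fs
  x <- sin(2 * pi * 50 * t + 0.6 * pi)
  f <- frequency_features(x, fs)
  expect_lt(abs(f[["MNF"]] - 50), 2.5)
  expect_lt(abs(f[["MDF"]] - 50), 2.5)
  expect_lt(abs(f[["MOF"]] - 50), 2.5)
  expect_equal(f[["ZC"]], 100)
  expect_equal(unname(frequency_features(rep(0, 128), fs)), rep(0, 6))
})

test_that("band-limited noise has mean frequency near the band center", {
  fs <- 1000
  set.seed(18)
  mnfs <- vapply(1:100, function(i) {
    x <- bandpass_filter(rnorm(2816), fs, 20, 250)
    frequency_features(x, fs)[["MNF"]]
  }, numeric(1))
  expect_true(all(mnfs > 100 & mnfs < 170))
})

test_that("median frequency lies inside the occupied spectral range", {
  set.seed(19)
  for (i in 1:10) {
    x <- rnorm(512)
    ps <- painfeat:::welch_psd(x, 128)
    f <- frequency_features(x, 128)
    occ <- ps$freq[ps$spec > 0]
    expect_gte(f[["MDF"]], min(occ))
    expect_lte(f[["MDF"]], max(occ))
  }
})

test_that("HRV features are exact for constructed beat trains", {
  fs <- 500
  make_ecg <- function(peak_samples, n, noise = 0) {
    t <- (seq_len(n) - 1) / fs
    x <- rnorm(n, 0, noise)
    for (p in peak_samples)
      x <- x + exp(-((t - (p - 1) / fs)^2) / (2 * 0.01^2))
    x
  }
  # perfectly periodic: RR 800 ms
  peaks <- seq(100, 2700, by = 400)
  set.seed(20)
  f <- hrv_features(make_ecg(peaks, 2750), fs)
  expect_equal(f[["MNRR"]], 800)
  expect_equal(f[["RMSSD"]], 0)
  expect_equal(f[["slopeRR"]], 0)
  # RR sequence 800, 810, 820 ms
  peaks2 <- c(100, 100 + 400, 100 + 400 + 405, 100 + 400 + 405 + 410)
  f2 <- hrv_features(make_ecg(peaks2, 1500), fs)
  expect_equal(f2[["MNRR"]], 810)
  expect_equal(f2[["RMSSD"]], 10)
  expect_equal(f2[["slopeRR"]], 10)
  # sparse windows yield flagged zeros
  f3 <- hrv_features(make_ecg(c(100, 500), 700), fs)
  expect_equal(as.numeric(f3), c(0, 0, 0))
  expect_true(attr(f3, "hrv_sparse"))
})

test_that("R-peak detection recovers constructed beat times under noise", {
  prof <- synth_subject_profile("S1", 33)
  hits <- 0; total <- 0
  for (i in 1:10) {
    tr <- synth_trial(prof, "B", "t", fs = 512, seed = 600 + i,
                      powerline_amp = 0)
    det <- detect_r_peaks(tr$channels$ECG, 512)
    truth <- round(tr$beat_times * 512) + 1
    total <- total + length(truth)
    for (p in truth) if (any(abs(det - p) <= 1)) hits <- hits + 1
  }
  expect_equal(hits, total)
})

test_that("closed-form features match brute-force oracles on random signals", {
  set.seed(21)
  for (i in 1:50) {
    x <- rnorm(256) * runif(1, 0.5, 20) + runif(1, -5, 5)
    expect_equal(amplitude_features(x), oracle_amplitude(x), tolerance = 1e-9)
    expect_equal(variability_features(x), oracle_variability(x),
                 tolerance = 1e-9)
    expect_equal(entropy_features(x, n_bins = 16)[["ShannonEn"]],
                 oracle_shannon(x, 16), tolerance = 1e-9)
    f <- frequency_features(x, 64)
    o <- oracle_frequency(x, 64)
    expect_equal(f, o, tolerance = 1e-9)
  }
})

test_that("histogram mutual information matches its double-loop oracle", {
  set.seed(22)
  for (i in 1:10) {
    a <- rnorm(300); b <- a * 0.5 + rnorm(300)
    expect_equal(similarity_features(a, b, fs = 64)[["MI"]],
                 oracle_hist_mi(a, b, 16), tolerance = 1e-9)
  }
})

test_that("template entropies match brute-force oracles", {
  set.seed(23)
  for (i in 1:15) {
    x <- rnorm(120)
    r <- 0.2 * sd(x)
    f <- entropy_features(x)
    expect_equal(f[["ApEn"]], oracle_apen(x, 2, r), tolerance = 1e-6)
    expect_equal(f[["SampEn"]], oracle_sampen(x, 2, r), tolerance = 1e-6)
    expect_equal(f[["FuzzyEn"]], oracle_fuzzyen(x, 2, r), tolerance = 1e-6)
  }
})

test_that("features scale as declared under amplitude scaling", {
  set.seed(24)
  x <- rnorm(512)
  a <- 3.7
  linear <- c("MAV", "RMS", "PK", "P2P")
  f1 <- amplitude_features(x); f2 <- amplitude_features(a * x)
  expect_equal(unname(f2[linear]), a * unname(f1[linear]), tolerance = 1e-9)
  v1 <- variability_features(x); v2 <- variability_features(a * x)
  expect_equal(v2[["SD"]], a * v1[["SD"]], tolerance = 1e-9)
  expect_equal(v2[["VAR"]], a^2 * v1[["VAR"]], tolerance = 1e-9)
  expect_equal(v2[["R"]], a * v1[["R"]], tolerance = 1e-9)
  expect_equal(v2[["IQR"]], a * v1[["IQR"]], tolerance = 1e-9)
  # scale-invariant features
  expect_equal(frequency_features(a * x, 128)[["ZC"]],
               frequency_features(x, 128)[["ZC"]])
  expect_equal(entropy_features(a * x, n_bins = 16)[["ShannonEn"]],
               entropy_features(x, n_bins = 16)[["ShannonEn"]],
               tolerance = 1e-9)
  set.seed(25)
  ref <- rnorm(512)
  expect_equal(similarity_features(a * x, ref, 128)[["CC"]],
               similarity_features(x, ref, 128)[["CC"]], tolerance = 1e-9)
  expect_equal(similarity_features(a * x, ref, 128)[["MNCOH"]],
               similarity_features(x, ref, 128)[["MNCOH"]], tolerance = 1e-9)
})

test_that("a full extraction yields 155 finite named values", {
  fx <- fixture_trial_pair()
  fv <- extract_features(fx$trial, fx$ref, fx$config)
  expect_equal(length(fv), 155)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  expect_equal(sum(startsWith(names(fv), "c")), 39)
  expect_equal(sum(startsWith(names(fv), "s")), 35)
  expect_equal(sum(startsWith(names(fv), "h")), 3)
  expect_identical(attr(fv, "level"), "T4")
  # mismatched subject is rejected
  other <- synth_subject_profile("S999", 1)
  bad_ref <- synth_trial(other, "B", "r", fs = fx$trial$fs, seed = 1,
                         emg_band = c(20, 55))
  expect_error(extract_features(fx$trial, bad_ref, fx$config), "subject")
})

test_that("z-scoring fits on the requested rows only", {
  fm <- synth_feature_matrix(4, 5, seed = 30)
  z <- zscore_normalize(fm)
  expect_equal(max(abs(colMeans(z$values))), 0, tolerance = 1e-12)
  sds <- apply(z$values, 2, sd)
  expect_equal(max(abs(sds - 1)), 0, tolerance = 1e-12)
  expect_identical(z$normalization, "zscored")

  # constant column maps to zero without NaN
  fm2 <- fm
  fm2$values[, 1] <- 7
  z2 <- zscore_normalize(fm2)
  expect_true(all(z2$values[, 1] == 0))
  expect_false(any(is.na(z2$values)))

  # fitting on a shifted half leaves held-out means off zero
  fm3 <- fm
  half <- seq_len(nrow(fm3$values) / 2)
  fm3$values[-half, ] <- fm3$values[-half, ] + 5
  z3 <- zscore_normalize(fm3, fit_rows = half)
  expect_gt(mean(abs(colMeans(z3$values[-half, , drop = FALSE]))), 1)
  expect_error(zscore_normalize(fm, fit_rows = integer(0)), "non-empty")
  expect_error(zscore_normalize(z), "already")
})
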