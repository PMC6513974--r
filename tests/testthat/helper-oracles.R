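# Brute-force reference implementations, written as direct transcriptions of
# the definitions (explicit loops, no shared code with the package). Used to
# verify the closed-form features.

oracle_amplitude <- function(x) {
  n <- length(x)
  mav <- sum(abs(x)) / n
  d1 <- x[2:n] - x[1:(n - 1)]
  d2 <- d1[2:(n - 1)] - d1[1:(n - 2)]
  homav1 <- sum(abs(d1)) / (n - 1)
  homav2 <- sum(abs(d2)) / (n - 2)
  peaks <- c(); valleys <- c()
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) peaks <- c(peaks, i)
    if (x[i] < x[i - 1] && x[i] < x[i + 1]) valleys <- c(valleys, i)
  }
  c(MAV = mav,
    RMS = sqrt(sum(x^2) / n),
    PK = max(abs(x)),
    P2P = max(x) - min(x),
    HOMAV1 = homav1,
    HOMAV1n = if (mav > 0) homav1 / mav else 0,
    HOMAV2 = homav2,
    HOMAV2n = if (mav > 0) homav2 / mav else 0,
    TMNP = if (length(peaks)) sum((peaks - 1) / (n - 1)) / length(peaks) else 0,
    TMNV = if (length(valleys)) sum((valleys - 1) / (n - 1)) / length(valleys) else 0)
}

oracle_quantile_type7 <- function(x, p) {
  xs <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, length(x))] - xs[lo])
}

oracle_variability <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / (n - 1)
  c(VAR = v, SD = sqrt(v), R = max(x) - min(x),
    IQR = oracle_quantile_type7(x, 0.75) - oracle_quantile_type7(x, 0.25))
}

oracle_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- 0
      for (k in 0:(m - 1)) dm <- max(dm, abs(x[i + k] - x[j + k]))
      if (dm <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(0)
  -log(A / B)
}

oracle_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    total <- 0
    for (i in 1:nt) {
      cnt <- 0
      for (j in 1:nt) {
        d <- 0
        for (k in 0:(mm - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= r) cnt <- cnt + 1
      }
      total <- total + log(cnt / nt)
    }
    total / nt
  }
  phi(m) - phi(m + 1)
}

oracle_fuzzyen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  phi <- function(mm) {
    acc <- 0
    for (i in 1:(nt - 1)) {
      for (j in (i + 1):nt) {
        d <- 0
        for (k in 0:(mm - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        acc <- acc + exp(-(d / r)^2)
      }
    }
    acc / (nt * (nt - 1) / 2)
  }
  log(phi(m)) - log(phi(m + 1))
}

oracle_shannon <- function(x, n_bins) {
  lo <- min(x); hi <- max(x)
  counts <- rep(0, n_bins)
  for (v in x) {
    b <- floor((v - lo) / (hi - lo) * n_bins) + 1
    if (b > n_bins) b <- n_bins
    counts[b] <- counts[b] + 1
  }
  p <- counts / sum(counts)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

# Welch periodogram, direct transcription: Hamming window, mean removal per
# segment, one-sided doubling
oracle_welch_psd <- function(x, fs, seg = round(fs / 2), overlap = 0.5) {
  n <- length(x)
  seg <- min(seg, n)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(seg - 1)) / (seg - 1))
  step <- round(seg * (1 - overlap))
  starts <- seq(1, n - seg + 1, by = step)
  nb <- floor(seg / 2) + 1
  acc <- rep(0, nb)
  for (s in starts) {
    xs <- x[s:(s + seg - 1)]
    xs <- (xs - mean(xs)) * w
    for (b in 1:nb) {
      X <- sum(xs * exp(-2i * pi * (b - 1) * (0:(seg - 1)) / seg))
      acc[b] <- acc[b] + Mod(X)^2
    }
  }
  spec <- acc / (sum(w^2) * length(starts))
  if (nb > 2) spec[2:(nb - 1)] <- 2 * spec[2:(nb - 1)]
  list(freq = (0:(nb - 1)) * fs / seg, spec = spec)
}

oracle_frequency <- function(x, fs) {
  s <- sign(x); s <- s[s != 0]
  zc <- 0
  if (length(s) > 1) for (i in 2:length(s)) if (s[i] != s[i - 1]) zc <- zc + 1
  ps <- oracle_welch_psd(x, fs)
  P <- ps$spec; f <- ps$freq; tot <- sum(P)
  if (tot == 0) return(c(MNF = 0, MDF = 0, MOF = 0, BW = 0, CF = 0, ZC = zc))
  mnf <- sum(f * P) / tot
  cum <- cumsum(P); half <- tot / 2
  i <- which(cum >= half)[1]
  mdf <- if (i == 1) f[1] else
    f[i - 1] + (half - cum[i - 1]) / (cum[i] - cum[i - 1]) * (f[i] - f[i - 1])
  c(MNF = mnf, MDF = mdf, MOF = f[which.max(P)],
    BW = sqrt(sum((f - mnf)^2 * P) / tot),
    CF = sqrt(sum(f^2 * P) / tot), ZC = zc)
}

oracle_coherence <- function(x, y, fs, seg = round(fs / 2), overlap = 0.5) {
  n <- length(x)
  seg <- min(seg, n)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(seg - 1)) / (seg - 1))
  step <- round(seg * (1 - overlap))
  starts <- seq(1, n - seg + 1, by = step)
  nb <- floor(seg / 2) + 1
  sxx <- rep(0, nb); syy <- rep(0, nb); sxy <- rep(0 + 0i, nb)
  for (s in starts) {
    xs <- x[s:(s + seg - 1)]; ys <- y[s:(s + seg - 1)]
    xs <- (xs - mean(xs)) * w; ys <- (ys - mean(ys)) * w
    for (b in 1:nb) {
      e <- exp(-2i * pi * (b - 1) * (0:(seg - 1)) / seg)
      X <- sum(xs * e); Y <- sum(ys * e)
      sxx[b] <- sxx[b] + Mod(X)^2
      syy[b] <- syy[b] + Mod(Y)^2
      sxy[b] <- sxy[b] + X * Conj(Y)
    }
  }
  coh <- rep(0, nb)
  for (b in 1:nb) if (sxx[b] * syy[b] > 0)
    coh[b] <- Mod(sxy[b])^2 / (sxx[b] * syy[b])
  list(freq = (0:(nb - 1)) * fs / seg, coherence = coh)
}

oracle_hist_mi <- function(a, b, n_bins) {
  ra <- range(a); rb <- range(b)
  bin <- function(v, r) min(floor((v - r[1]) / (r[2] - r[1]) * n_bins) + 1, n_bins)
  joint <- matrix(0, n_bins, n_bins)
  for (i in seq_along(a)) {
    ba <- bin(a[i], ra); bb <- bin(b[i], rb)
    joint[ba, bb] <- joint[ba, bb] + 1
  }
  joint <- joint / length(a)
  pa <- rowSums(joint); pb <- colSums(joint)
  mi <- 0
  for (i in 1:n_bins) for (j in 1:n_bins)
    if (joint[i, j] > 0)
      mi <- mi + joint[i, j] * log(joint[i, j] / (pa[i] * pb[j]))
  max(mi, 0)
}

oracle_anova_f <- function(values, labels) {
  fit <- stats::lm(values ~ factor(labels))
  stats::anova(fit)[["F value"]][1]
}

oracle_knn_lens <- function(D, k) {
  n <- nrow(D)
  out <- numeric(n)
  for (i in 1:n) {
    d <- D[i, -i]
    out[i] <- sort(d)[k]
  }
  out
}

oracle_euclidean <- function(M) {
  n <- nrow(M)
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    D[i, j] <- sqrt(sum((M[i, ] - M[j, ])^2))
  D
}
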