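# construct the pf_feature_matrix container (rows = trials, columns = the
# 155 registry features in canonical order)
new_feature_matrix <- function(values, meta, normalization = "raw") {
  nm <- feature_names()
  stopifnot(identical(colnames(values), nm), nrow(values) == nrow(meta))
  structure(list(values = values, meta = meta, normalization = normalization),
            class = "pf_feature_matrix")
}

#' @export
print.pf_feature_matrix <- function(x, ...) {
  cat(sprintf("<pf_feature_matrix> %d trials x %d features (%s), %d subjects, levels: %s\n",
              nrow(x$values), ncol(x$values), x$normalization,
              length(unique(x$meta$subject_id)),
              paste(sort(unique(x$meta$level)), collapse = " ")))
  invisible(x)
}

# per-channel feature block (the 39 continuous-channel features), named by
# base abbreviation
.channel_features <- function(x, ref, fs, hs, band, config) {
  psd <- welch_psd(x, fs)
  c(amplitude_features(x),
    variability_features(x),
    stationarity_features(x, fs, config$n_segments, hs),
    entropy_features(x, config$m, config$r_frac, config$n_bins, fs, psd = psd),
    linearity_features(x, config$max_lag, config$n_bins),
    similarity_features(x, ref, fs, band, config$n_bins),
    frequency_features(x, fs, psd = psd))
}

#' Extract the 155-feature vector of one trial
#'
#' Preprocesses the trial and its subject's pain-free baseline recording,
#' then computes every registry feature: 39 per EMG channel, 35 for SCL
#' (BW, CF, MOF, ZC are not defined for the electrodermal channel), and the
#' 3 HRV features for ECG. Similarity features compare the trial window
#' against the baseline recording of the same channel. Any non-finite value
#' produced by a degenerate input is mapped to 0, so the returned vector is
#' always finite.
#'
#' @param trial A `pf_trial`.
#' @param baseline_ref The subject's baseline reference `pf_trial` (same
#'   subject, sampling rate, and duration).
#' @param config See [feature_config()].
#' @param pre,pre_ref Optional pre-computed [preprocess_trial()] results
#'   (the pipeline preprocesses each subject's baseline once and reuses it).
#' @return Named numeric vector of the 155 features in registry order, with
#'   attributes `subject_id`, `trial_id`, `level`.
#' @export
extract_features <- function(trial, baseline_ref, config = feature_config(),
                             pre = NULL, pre_ref = NULL) {
  if (is.null(pre)) {
    stopifnot(inherits(trial, "pf_trial"), inherits(baseline_ref, "pf_trial"))
    if (trial$subject_id != baseline_ref$subject_id)
      stop("trial and baseline_ref must share the subject")
    if (trial$fs != baseline_ref$fs)
      stop("trial and baseline_ref must share the sampling rate")
    pre <- preprocess_trial(trial, config$pre)
  }
  if (is.null(pre_ref)) pre_ref <- preprocess_trial(baseline_ref, config$pre)
  fs <- pre$fs
  emg_band <- .cap_band(config$pre$emg_band, fs)
  reg <- feature_registry()
  vals <- numeric(nrow(reg))
  names(vals) <- reg$name
  for (ch in c("zEMG", "cEMG", "tEMG", "SCL")) {
    band <- if (ch == "SCL") config$scl_band else emg_band
    block <- .channel_features(pre$channels[[ch]], pre_ref$channels[[ch]],
                               fs, pre$hspec[[ch]], band, config)
    rows <- reg$channel == ch
    vals[rows] <- block[reg$abbrev[rows]]
  }
  hb <- hrv_features(pre$channels$ECG, fs)
  vals[reg$channel == "ECG"] <- hb[reg$abbrev[reg$channel == "ECG"]]
  vals[!is.finite(vals)] <- 0
  attr(vals, "subject_id") <- pre$subject_id
  attr(vals, "trial_id") <- pre$trial_id
  attr(vals, "level") <- pre$level
  vals
}

#' Build the feature matrix of a synthetic dataset
#'
#' Runs [extract_features()] for every counted trial against its subject's
#' baseline reference (each baseline is preprocessed once).
#'
#' @param dataset From [synth_dataset()].
#' @param config See [feature_config()].
#' @param verbose Print progress every 500 trials.
#' @return A `pf_feature_matrix` in raw state.
#' @export
build_feature_matrix <- function(dataset, config = feature_config(),
                                 verbose = FALSE) {
  trials <- dataset$trials
  pre_refs <- lapply(dataset$baselines, preprocess_trial, config = config$pre)
  n <- length(trials)
  vals <- matrix(NA_real_, n, 155, dimnames = list(NULL, feature_names()))
  meta <- data.frame(subject_id = character(n), trial_id = character(n),
                     level = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tr <- trials[[i]]
    fv <- extract_features(tr, dataset$baselines[[tr$subject_id]],
                           config = config,
                           pre = preprocess_trial(tr, config$pre),
                           pre_ref = pre_refs[[tr$subject_id]])
    vals[i, ] <- fv
    meta$subject_id[i] <- attr(fv, "subject_id")
    meta$trial_id[i] <- attr(fv, "trial_id")
    meta$level[i] <- attr(fv, "level")
    if (verbose && i %% 500 == 0)
      message(sprintf("extracted %d / %d trials", i, n))
  }
  new_feature_matrix(vals, meta)
}

#' Stream a roster through generation, preprocessing, and extraction
#'
#' Generates each trial on the fly and extracts its features immediately,
#' so full-roster runs (thousands of trials) never hold all recordings in
#' memory. Baseline references are generated and preprocessed once per
#' subject.
#'
#' @param roster A [make_roster()] object.
#' @param fs,effects,powerline_amp,emg_band Passed to [synth_trial()].
#' @param config See [feature_config()].
#' @param verbose Print progress every 1000 trials.
#' @return A `pf_feature_matrix` in raw state.
#' @export
extract_roster_features <- function(roster, fs = 512,
                                    effects = default_effects(),
                                    powerline_amp = 1,
                                    emg_band = c(20, 250),
                                    config = feature_config(
                                      pre = preprocess_config(emg_band = emg_band)),
                                    verbose = FALSE) {
  stopifnot(inherits(roster, "pf_roster"))
  tr <- roster$trials
  refs <- tr[tr$is_baseline_ref, ]
  pre_refs <- list()
  for (i in seq_len(nrow(refs))) {
    row <- refs[i, ]
    ref <- synth_trial(roster$profiles[[row$subject_id]], row$level,
                       row$trial_id, fs = fs, seed = row$seed,
                       effects = effects, powerline_amp = powerline_amp,
                       emg_band = emg_band)
    pre_refs[[row$subject_id]] <- preprocess_trial(ref, config$pre)
  }
  main <- tr[!tr$is_baseline_ref, ]
  n <- nrow(main)
  vals <- matrix(NA_real_, n, 155, dimnames = list(NULL, feature_names()))
  for (i in seq_len(n)) {
    row <- main[i, ]
    vals[i, ] <- tryCatch({
      trial <- synth_trial(roster$profiles[[row$subject_id]], row$level,
                           row$trial_id, fs = fs, seed = row$seed,
                           effects = effects, powerline_amp = powerline_amp,
                           emg_band = emg_band)
      extract_features(trial, NULL, config = config,
                       pre = preprocess_trial(trial, config$pre),
                       pre_ref = pre_refs[[row$subject_id]])
    }, error = function(e) {
      stop("trial ", row$trial_id, " (subject ", row$subject_id, "): ",
           conditionMessage(e), call. = FALSE)
    })
    if (verbose && i %% 1000 == 0)
      message(sprintf("extracted %d / %d trials", i, n))
  }
  meta <- data.frame(subject_id = main$subject_id, trial_id = main$trial_id,
                     level = main$level, stringsAsFactors = FALSE)
  new_feature_matrix(vals, meta)
}

#' Z-score normalize a feature matrix
#'
#' Per-column mean and SD are estimated on `fit_rows` only and applied to
#' all rows (so cross-validation folds can normalize without leakage).
#' Columns constant on the fit rows map to 0.
#'
#' @param matrix A `pf_feature_matrix` in raw state.
#' @param fit_rows Row indices used to estimate the normalization (default
#'   all rows).
#' @return A `pf_feature_matrix` with `normalization = "zscored"` and
#'   attributes `center` and `scale`.
#' @export
zscore_normalize <- function(matrix, fit_rows = seq_len(nrow(matrix$values))) {
  stopifnot(inherits(matrix, "pf_feature_matrix"))
  if (!length(fit_rows)) stop("fit_rows must be non-empty")
  if (matrix$normalization != "raw") stop("matrix is already normalized")
  sub <- matrix$values[fit_rows, , drop = FALSE]
  ctr <- colMeans(sub)
  scl <- apply(sub, 2, stats::sd)
  vals <- sweep(matrix$values, 2, ctr, "-")
  ok <- is.finite(scl) & scl > 0
  vals[, ok] <- sweep(vals[, ok, drop = FALSE], 2, scl[ok], "/")
  vals[, !ok] <- 0
  out <- new_feature_matrix(vals, matrix$meta, normalization = "zscored")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}
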