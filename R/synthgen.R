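#' Pain levels
#'
#' The five stimulus levels of the calibrated heat-pain protocol: baseline
#' (`B`, 32 degrees C), pain threshold (`T1`), two intermediate levels
#' (`T2`, `T3`), and pain tolerance (`T4`). Ordinals run 0 (B) to 4 (T4).
#'
#' @return Character vector `c("B","T1","T2","T3","T4")`.
#' @export
pain_levels <- function() c("B", "T1", "T2", "T3", "T4")

#' Ordinal position of a pain level
#'
#' @param level Character vector of level labels.
#' @return Integer ordinal(s), 0 for `B` through 4 for `T4`.
#' @export
level_ordinal <- function(level) {
  ord <- match(level, pain_levels()) - 1L
  if (anyNA(ord)) stop("unknown pain level: ", paste(level[is.na(ord)], collapse = ", "))
  ord
}

# draw sub-seeds below 2^31 from a parent seed without disturbing the
# caller's RNG state
.derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Default generator level effects
#'
#' Standardized (Cohen's d) level effects on each channel's driving
#' parameter, expressed as the baseline-to-tolerance (B vs T4) effect size.
#' The facial EMG channels respond more strongly than the trapezius; the
#' skin-conductance phasic response increases with level; mean heart rate
#' decreases slightly (hence the negative sign).
#'
#' @param zEMG,cEMG,tEMG,SCL,HR Per-channel effect sizes.
#' @return Named list of effect sizes.
#' @export
default_effects <- function(zEMG = 0.6, cEMG = 0.6, tEMG = 0.35,
                            SCL = 0.6, HR = -0.35) {
  list(zEMG = zEMG, cEMG = cEMG, tEMG = tEMG, SCL = SCL, HR = HR)
}

#' Null-mode generator effects (all level effects zero)
#'
#' Under the null mode the five levels are exchangeable, which is the basis
#' of the type-I-error calibration experiments.
#'
#' @return Named list of zero effect sizes.
#' @export
null_effects <- function() default_effects(0, 0, 0, 0, 0)

#' Synthesize a subject profile
#'
#' Per-subject response calibration: multiplicative response gains per
#' channel drawn from a log-normal with median 1, a resting heart rate
#' uniform in [55, 95] beats/min, a tonic skin-conductance baseline, and
#' small additive per-channel offsets acting as subject random effects on
#' the driving parameters. Fully deterministic given `seed`.
#'
#' @param subject_id Identifier.
#' @param seed Integer seed.
#' @param gain_sigma Log-scale SD of the gain distribution (default 0.25).
#' @return An object of class `pf_subject`.
#' @export
synth_subject_profile <- function(subject_id, seed, gain_sigma = 0.25) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  .with_seed(seed, {
    gains <- stats::rlnorm(5, meanlog = 0, sdlog = gain_sigma)
    names(gains) <- c("zEMG", "cEMG", "tEMG", "SCL", "ECG")
    prof <- list(
      subject_id = as.character(subject_id),
      gain = gains,
      offset = stats::rnorm(4, 0, 0.15),
      hr_baseline = stats::runif(1, 55, 95),
      scl_tonic_baseline = stats::runif(1, 2, 10),
      rng_seed = as.integer(seed)
    )
    names(prof$offset) <- c("zEMG", "cEMG", "tEMG", "SCL")
    class(prof) <- "pf_subject"
    prof
  })
}

#' @export
print.pf_subject <- function(x, ...) {
  cat("<pf_subject>", x$subject_id,
      sprintf("hr %.1f bpm, tonic SCL %.2f uS, seed %d\n",
              x$hr_baseline, x$scl_tonic_baseline, x$rng_seed))
  invisible(x)
}

#' Build a dataset roster
#'
#' Enumerates every (subject, level, trial) combination exactly once, plus
#' one extra baseline-level reference recording per subject (used as the
#' pain-free reference of the similarity features; it is not one of the
#' counted trials). Subject profiles and all per-trial seeds are derived
#' deterministically from `master_seed`.
#'
#' @param n_subjects Number of subjects (study default 85).
#' @param trials_per_level Trials per subject per level (study default 20).
#' @param master_seed Integer master seed.
#' @return An object of class `pf_roster` with elements `trials` (data.frame
#'   with `subject_id`, `trial_id`, `level`, `ordinal`, `seed`, `is_baseline_ref`),
#'   `profiles` (list of [synth_subject_profile()] objects), and `master_seed`.
#' @examples
#' r <- make_roster(2, 3, master_seed = 7)
#' sum(!r$trials$is_baseline_ref)  # 2 * 5 * 3 = 30
#' @export
make_roster <- function(n_subjects = 85, trials_per_level = 20, master_seed = 1) {
  if (n_subjects < 1 || trials_per_level < 1)
    stop("n_subjects and trials_per_level must be positive")
  subj_ids <- sprintf("S%03d", seq_len(n_subjects))
  seeds <- .derive_seeds(master_seed,
                         n_subjects + n_subjects * (5L * trials_per_level + 1L))
  prof_seeds <- seeds[seq_len(n_subjects)]
  trial_seeds <- seeds[-seq_len(n_subjects)]
  profiles <- lapply(seq_len(n_subjects), function(i)
    synth_subject_profile(subj_ids[i], prof_seeds[i]))
  names(profiles) <- subj_ids

  grid <- expand.grid(trial = seq_len(trials_per_level), level = pain_levels(),
                      subject_id = subj_ids, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$subject_id, subj_ids),
                     match(grid$level, pain_levels()), grid$trial), ]
  trials <- data.frame(
    subject_id = grid$subject_id,
    trial_id = sprintf("%s_%s_%02d", grid$subject_id, grid$level, grid$trial),
    level = grid$level,
    ordinal = level_ordinal(grid$level),
    is_baseline_ref = FALSE,
    stringsAsFactors = FALSE
  )
  refs <- data.frame(
    subject_id = subj_ids,
    trial_id = sprintf("%s_ref", subj_ids),
    level = "B", ordinal = 0L, is_baseline_ref = TRUE,
    stringsAsFactors = FALSE
  )
  trials <- rbind(trials, refs)
  trials <- trials[order(match(trials$subject_id, subj_ids), !trials$is_baseline_ref,
                         match(trials$level, pain_levels())), ]
  trials$seed <- trial_seeds[seq_len(nrow(trials))]
  rownames(trials) <- NULL
  structure(list(trials = trials, profiles = profiles,
                 n_subjects = n_subjects, trials_per_level = trials_per_level,
                 master_seed = as.integer(master_seed)),
            class = "pf_roster")
}

#' @export
print.pf_roster <- function(x, ...) {
  cat(sprintf("<pf_roster> %d subjects x 5 levels x %d trials = %d trials (+%d baseline refs), master seed %d\n",
              x$n_subjects, x$trials_per_level,
              sum(!x$trials$is_baseline_ref), sum(x$trials$is_baseline_ref),
              x$master_seed))
  invisible(x)
}

# zero-phase band-limited Gaussian noise with unit RMS
.bandnoise <- function(n, fs, band) {
  x <- stats::rnorm(n + 2L * fs)  # pad to absorb filter edge effects
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  y <- .zp_filter(bf, x)[(fs + 1):(fs + n)]
  y / sqrt(mean(y^2))
}

# Bateman (bi-exponential) skin conductance response kernel, peak-normalized
.bateman <- function(t, tau_rise = 0.75, tau_decay = 3) {
  h <- ifelse(t < 0, 0, exp(-t / tau_decay) - exp(-t / tau_rise))
  pk <- max(h)
  if (pk > 0) h / pk else h
}

#' Synthesize one multimodal trial recording
#'
#' Generates the five synchronized channels of one trial:
#' \itemize{
#'   \item EMG (`zEMG`, `cEMG`, `tEMG`): band-limited Gaussian noise whose
#'     amplitude scales with the pain-level ordinal times the subject's gain;
#'     the facial channels carry larger level effects than the trapezius.
#'   \item SCL: tonic baseline plus a pain-triggered phasic response with a
#'     bi-exponential (Bateman) kernel whose amplitude increases with level.
#'   \item ECG: a Gaussian-bump QRS template train whose mean rate decreases
#'     slightly with level.
#' }
#' All channels receive an additive power-line sinusoid (`line_freq`, default
#' 50 Hz) scaled by `powerline_amp`. Channels are bit-reproducible given
#' identical arguments.
#'
#' Level effects are parameterized as Cohen's d between baseline and
#' tolerance on each channel's driving parameter (envelope amplitude, phasic
#' amplitude, mean heart rate), with the trial-to-trial SD of that parameter
#' as the standardizer.
#'
#' @param profile A [synth_subject_profile()] object.
#' @param level Pain level label (`"B"` ... `"T4"`).
#' @param trial_id Identifier.
#' @param fs Sampling rate in Hz (default 512; must exceed twice the upper
#'   EMG band edge).
#' @param duration Recording length in seconds (default 5.5, the response
#'   window).
#' @param seed Integer seed.
#' @param effects Level effects, see [default_effects()].
#' @param powerline_amp Multiplier on the per-channel power-line amplitude
#'   (0 disables contamination).
#' @param emg_band EMG synthesis band in Hz (default `c(20, 250)`).
#' @param line_freq Power-line frequency in Hz.
#' @return An object of class `pf_trial`: list with `subject_id`, `trial_id`,
#'   `level`, `channels` (named list of numeric vectors), `fs`, `duration`,
#'   `stimulus_onset` (0: the recording is the response window).
#' @export
synth_trial <- function(profile, level, trial_id, fs = 512, duration = 5.5,
                        seed = 1, effects = default_effects(),
                        powerline_amp = 1, emg_band = c(20, 250),
                        line_freq = 50) {
  stopifnot(inherits(profile, "pf_subject"))
  if (fs <= 2 * emg_band[2])
    stop("fs must exceed twice the upper EMG band edge (", 2 * emg_band[2],
         " Hz): Nyquist violation")
  if (duration < 5.5) stop("duration must be at least 5.5 s")
  ord <- level_ordinal(level)
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs

  .with_seed(seed, {
    sigma <- 0.25  # trial-to-trial SD of the relative driving amplitude
    chans <- list()
    base_amp <- c(zEMG = 30, cEMG = 30, tEMG = 20)
    for (ch in c("zEMG", "cEMG", "tEMG")) {
      drive <- 1 + effects[[ch]] * sigma * ord / 4 +
        profile$offset[[ch]] * sigma + stats::rnorm(1, 0, sigma)
      drive <- max(drive, 0.05)
      amp <- base_amp[[ch]] * profile$gain[[ch]] * drive
      chans[[ch]] <- amp * .bandnoise(n, fs, emg_band)
    }

    # SCL: tonic + drift + phasic Bateman response from stimulus onset
    scl_sigma <- 0.25
    phasic_drive <- 1 + effects$SCL * scl_sigma * ord / 4 +
      profile$offset[["SCL"]] * scl_sigma + stats::rnorm(1, 0, scl_sigma)
    phasic_amp <- 0.4 * profile$gain[["SCL"]] * max(phasic_drive, 0)
    drift <- stats::rnorm(1, 0, 0.02)
    chans$SCL <- profile$scl_tonic_baseline + drift * tt +
      phasic_amp * .bateman(tt - 0.8) + stats::rnorm(n, 0, 0.01)

    # ECG: QRS bumps at a level-dependent rate
    hr_sigma <- 0.8  # bpm
    hr <- profile$hr_baseline + effects$HR * hr_sigma * ord / 4 +
      stats::rnorm(1, 0, hr_sigma)
    hr <- max(hr, 30)
    rr_mean <- 60 / hr
    n_beats <- ceiling(duration / rr_mean) + 3L
    rr <- rr_mean + stats::rnorm(n_beats, 0, 0.010)
    beat_t <- 0.2 + cumsum(c(0, rr))
    beat_t <- beat_t[beat_t < duration - 0.02]
    ecg <- stats::rnorm(n, 0, 0.02)
    qrs_w <- 0.01  # Gaussian bump SD in seconds
    for (bt in beat_t) {
      idx <- which(abs(tt - bt) < 4 * qrs_w)
      ecg[idx] <- ecg[idx] + exp(-((tt[idx] - bt)^2) / (2 * qrs_w^2))
    }
    chans$ECG <- ecg

    if (powerline_amp > 0) {
      line_amp <- c(zEMG = 2, cEMG = 2, tEMG = 2, SCL = 0.02, ECG = 0.05)
      for (ch in names(chans)) {
        phase <- stats::runif(1, 0, 2 * pi)
        chans[[ch]] <- chans[[ch]] +
          powerline_amp * line_amp[[ch]] * sin(2 * pi * line_freq * tt + phase)
      }
    }

    structure(list(subject_id = profile$subject_id, trial_id = as.character(trial_id),
                   level = level, channels = chans, fs = fs, duration = duration,
                   stimulus_onset = 0, hr_true = hr, beat_times = beat_t),
              class = "pf_trial")
  })
}

#' @export
print.pf_trial <- function(x, ...) {
  cat(sprintf("<pf_trial> %s %s level %s: 5 channels x %d samples @ %g Hz\n",
              x$subject_id, x$trial_id, x$level,
              length(x$channels[[1]]), x$fs))
  invisible(x)
}

#' Synthesize a full dataset from a roster
#'
#' @param roster A [make_roster()] object.
#' @param fs,duration,effects,powerline_amp,emg_band Passed to [synth_trial()].
#' @return List with `trials` (list of `pf_trial`, counted trials only),
#'   `baselines` (named list of per-subject baseline reference recordings),
#'   and `roster`.
#' @export
synth_dataset <- function(roster, fs = 512, duration = 5.5,
                          effects = default_effects(), powerline_amp = 1,
                          emg_band = c(20, 250)) {
  stopifnot(inherits(roster, "pf_roster"))
  gen <- function(row) {
    synth_trial(roster$profiles[[row$subject_id]], row$level, row$trial_id,
                fs = fs, duration = duration, seed = row$seed,
                effects = effects, powerline_amp = powerline_amp,
                emg_band = emg_band)
  }
  tr <- roster$trials
  main <- tr[!tr$is_baseline_ref, ]
  refs <- tr[tr$is_baseline_ref, ]
  trials <- lapply(seq_len(nrow(main)), function(i) gen(main[i, ]))
  names(trials) <- main$trial_id
  baselines <- lapply(seq_len(nrow(refs)), function(i) gen(refs[i, ]))
  names(baselines) <- refs$subject_id
  list(trials = trials, baselines = baselines, roster = roster)
}

#' Write a synthetic dataset to disk
#'
#' One directory per dataset: per-trial channel CSVs (`time_s`, `zEMG`,
#' `cEMG`, `tEMG`, `SCL`, `ECG`), a roster manifest JSON (subject, trial,
#' level, seed, fs), and a config JSON.
#'
#' @param dataset From [synth_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_tr <- c(dataset$trials, dataset$baselines)
  for (tr in all_tr) {
    n <- length(tr$channels[[1]])
    df <- data.frame(time_s = (seq_len(n) - 1) / tr$fs, tr$channels,
                     check.names = FALSE)
    utils::write.csv(df, file.path(dir, paste0(tr$trial_id, ".csv")),
                     row.names = FALSE)
  }
  manifest <- dataset$roster$trials
  manifest$fs <- all_tr[[1]]$fs
  jsonlite::write_json(manifest, file.path(dir, "roster.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  cfg <- list(n_subjects = dataset$roster$n_subjects,
              trials_per_level = dataset$roster$trials_per_level,
              master_seed = dataset$roster$master_seed,
              fs = all_tr[[1]]$fs, duration = all_tr[[1]]$duration)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Synthesize a feature-level dataset with designated informative columns
#'
#' A companion generator operating directly at the feature-matrix level:
#' every registry feature is drawn as subject random intercept plus unit
#' Gaussian noise, and designated columns additionally carry a linear level
#' effect whose baseline-vs-tolerance standardized size (Cohen's d) is exact
#' by construction. Used for selection-recovery and interaction band-recovery
#' experiments where the injected effect size must be known on the feature
#' scale itself.
#'
#' @param n_subjects,trials_per_level Roster dimensions.
#' @param informative Named numeric vector: registry feature name -> Cohen's
#'   d between B and T4 (sign gives direction). Empty for a null matrix.
#' @param seed Integer seed.
#' @param subject_sd SD of the per-feature subject random intercepts.
#' @return A `pf_feature_matrix` (raw state) over all 155 registry features.
#' @export
synth_feature_matrix <- function(n_subjects, trials_per_level,
                                 informative = numeric(0), seed = 1,
                                 subject_sd = 0.5) {
  nm <- feature_names()
  if (length(informative) && !all(names(informative) %in% nm))
    stop("unknown feature name(s): ",
         paste(setdiff(names(informative), nm), collapse = ", "))
  levels <- rep(pain_levels(), each = trials_per_level)
  subj <- sprintf("S%03d", seq_len(n_subjects))
  meta <- data.frame(
    subject_id = rep(subj, each = length(levels)),
    trial_id = paste0(rep(subj, each = length(levels)), "_",
                      rep(seq_along(levels), n_subjects)),
    level = rep(levels, n_subjects),
    stringsAsFactors = FALSE
  )
  n <- nrow(meta)
  .with_seed(seed, {
    vals <- matrix(stats::rnorm(n * length(nm)), n, length(nm),
                   dimnames = list(NULL, nm))
    subj_fx <- matrix(stats::rnorm(n_subjects * length(nm), 0, subject_sd),
                      n_subjects, length(nm))
    vals <- vals + subj_fx[match(meta$subject_id, subj), ]
    if (length(informative)) {
      ord <- level_ordinal(meta$level)
      for (f in names(informative))
        vals[, f] <- vals[, f] + informative[[f]] * ord / 4
    }
    new_feature_matrix(vals, meta)
  })
}
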