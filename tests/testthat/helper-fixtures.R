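# Shared small fixtures, built once per test run.

fixture_env <- new.env()

# one subject's trial + baseline at a reduced sampling rate, preprocessed
fixture_trial_pair <- function(fs = 128, emg_band = c(20, 55)) {
  key <- paste0("pair_", fs)
  if (is.null(fixture_env[[key]])) {
    prof <- synth_subject_profile("S001", 4242)
    trial <- synth_trial(prof, "T4", "trial1", fs = fs, seed = 101,
                         emg_band = emg_band)
    ref <- synth_trial(prof, "B", "ref1", fs = fs, seed = 102,
                       emg_band = emg_band)
    fixture_env[[key]] <- list(profile = prof, trial = trial, ref = ref,
                               config = feature_config(
                                 pre = preprocess_config(emg_band = emg_band)))
  }
  fixture_env[[key]]
}

# reduced-rate signal-level dataset feature matrix (shared across tests)
fixture_small_matrix <- function() {
  if (is.null(fixture_env$small_fm)) {
    roster <- make_roster(3, 4, master_seed = 77)
    ds <- synth_dataset(roster, fs = 128, emg_band = c(20, 55))
    cfg <- feature_config(pre = preprocess_config(emg_band = c(20, 55)))
    fixture_env$small_fm <- build_feature_matrix(ds, cfg)
  }
  fixture_env$small_fm
}

# build a small z-scored matrix whose feature columns form two well-separated
# blocks: `block` features are near-copies of one latent pattern, the rest are
# i.i.d. noise scaled to keep between-block distances large
two_block_matrix <- function(n_rows = 60, block = feature_names()[1:40],
                             seed = 1, jitter = 0.02) {
  set.seed(seed)
  latent <- rnorm(n_rows)
  vals <- matrix(rnorm(n_rows * 155), n_rows, 155,
                 dimnames = list(NULL, feature_names()))
  for (f in block) vals[, f] <- latent + rnorm(n_rows, 0, jitter)
  vals <- scale(vals)
  attr(vals, "scaled:center") <- NULL
  attr(vals, "scaled:scale") <- NULL
  meta <- data.frame(subject_id = rep("S1", n_rows),
                     trial_id = as.character(seq_len(n_rows)),
                     level = rep(pain_levels(), length.out = n_rows),
                     stringsAsFactors = FALSE)
  fm <- painfeat:::new_feature_matrix(vals, meta, normalization = "zscored")
  fm
}

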