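#' Pipeline run configuration
#'
#' All parameters of an end-to-end run, serializable to JSON. The defaults
#' mirror the reference study protocol (85 subjects, 20 trials per level,
#' 512 Hz, 100 epochs); reduced values are the usual choice for desk-scale
#' runs.
#'
#' @param n_subjects,trials_per_level,master_seed Roster parameters.
#' @param fs Sampling rate, Hz.
#' @param effects Generator level effects, see [default_effects()].
#' @param powerline_amp Power-line contamination multiplier.
#' @param emg_band EMG band, Hz (generator and preprocessing).
#' @param feature Feature settings, see [feature_config()].
#' @param problems Problem names to run, see [classification_problem()].
#' @param n_epochs,sfs_iters,n_max Selection settings.
#' @param chart_k,chart_N,chart_L Mapper settings.
#' @return Named list of class `pf_config`.
#' @export
pipeline_config <- function(n_subjects = 85, trials_per_level = 20,
                            master_seed = 1, fs = 512,
                            effects = default_effects(), powerline_amp = 1,
                            emg_band = c(20, 250),
                            feature = feature_config(
                              pre = preprocess_config(emg_band = emg_band)),
                            problems = c("pain_threshold", "pain_tolerance",
                                         "three_class", "five_class"),
                            n_epochs = 100, sfs_iters = 8, n_max = 20,
                            chart_k = 2, chart_N = 4, chart_L = 0.5) {
  structure(list(n_subjects = n_subjects, trials_per_level = trials_per_level,
                 master_seed = master_seed, fs = fs, effects = effects,
                 powerline_amp = powerline_amp, emg_band = emg_band,
                 feature = feature, problems = problems, n_epochs = n_epochs,
                 sfs_iters = sfs_iters, n_max = n_max, chart_k = chart_k,
                 chart_N = chart_N, chart_L = chart_L),
            class = "pf_config")
}

#' Run the full pipeline
#'
#' Executes generation, preprocessing, feature extraction, selection over
#' the configured classification problems, Mapper charting, and the
#' interaction analysis; writes every output plus a manifest JSON with file
#' hashes. Identical configurations produce identical manifests.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param verbose Print per-stage progress.
#' @return The manifest as a list (invisibly also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "pf_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating %d subjects x %d trials/level and extracting features",
      config$n_subjects, config$trials_per_level)
  roster <- make_roster(config$n_subjects, config$trials_per_level,
                        config$master_seed)
  fm <- extract_roster_features(roster, fs = config$fs,
                                effects = config$effects,
                                powerline_amp = config$powerline_amp,
                                emg_band = config$emg_band,
                                config = config$feature, verbose = verbose)
  write_feature_matrix(fm, file.path(out_dir, "features.csv"))
  write_registry_json(file.path(out_dir, "registry.json"))

  say("running selection")
  sel_files <- character(0)
  results <- list()
  for (pname in config$problems) {
    sel <- run_selection(fm, pname, n_epochs = config$n_epochs,
                         seed = config$master_seed,
                         sfs_iters = config$sfs_iters, n_max = config$n_max)
    results[[pname]] <- sel
    rk <- data.frame(rank = seq_along(sel$ranking$features),
                     feature = sel$ranking$features,
                     mean_f = as.numeric(sel$ranking$mean_f))
    nmax <- length(sel$ufs_curve$n)
    rk$accuracy_mean <- c(sel$ufs_curve$mean,
                          rep(NA, nrow(rk) - nmax))[seq_len(nrow(rk))]
    rk$accuracy_sd <- c(sel$ufs_curve$sd,
                        rep(NA, nrow(rk) - nmax))[seq_len(nrow(rk))]
    f_rank <- file.path(out_dir, paste0("ranking_", pname, ".csv"))
    utils::write.csv(rk, f_rank, row.names = FALSE)
    f_vote <- file.path(out_dir, paste0("votes_", pname, ".csv"))
    utils::write.csv(sel$vote$table, f_vote, row.names = FALSE)
    f_curve <- file.path(out_dir, paste0("curve_", pname, ".csv"))
    utils::write.csv(data.frame(n = sel$sfs_curve$n,
                                accuracy_mean = sel$sfs_curve$mean,
                                accuracy_sd = sel$sfs_curve$sd),
                     f_curve, row.names = FALSE)
    sel_files <- c(sel_files, f_rank, f_vote, f_curve)
  }

  say("building the feature chart")
  zm <- zscore_normalize(fm)
  chart <- mapper_chart(zm, k = config$chart_k, N = config$chart_N,
                        L = config$chart_L)
  chart_path <- file.path(out_dir, "chart.graphml")
  write_chart_graphml(chart, chart_path)

  say("interaction analysis")
  inter <- interaction_table(fm)
  write_interaction_csv(inter, file.path(out_dir, "interaction_table.csv"),
                        file.path(out_dir, "interaction_long.csv"))

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  files <- c(file.path(out_dir, c("features.csv", "registry.json",
                                  "chart.graphml", "chart.json",
                                  "interaction_table.csv",
                                  "interaction_long.csv", "config.json")),
             sel_files)
  manifest <- list(
    config = unclass(config),
    n_trials = nrow(fm$values),
    n_features = ncol(fm$values),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, feature_matrix = fm, chart = chart,
                 interaction = inter, selection = results))
}

#' Write a feature matrix to CSV
#'
#' Metadata columns (`subject_id`, `trial_id`, `level`) followed by the 155
#' registry feature columns, full precision.
#'
#' @param matrix A `pf_feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(matrix, path) {
  df <- cbind(matrix$meta,
              as.data.frame(matrix$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' Columns may appear in any order; they are canonicalized to registry
#' order. Missing metadata or feature columns raise a format error naming
#' them.
#'
#' @param path CSV path written by [write_feature_matrix()].
#' @param normalization State to record (default `"raw"`).
#' @return A `pf_feature_matrix`.
#' @export
read_feature_matrix <- function(path, normalization = "raw") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("subject_id", "trial_id", "level")
  missing <- setdiff(c(meta_cols, feature_names()), names(df))
  if (length(missing))
    stop("feature matrix file lacks column(s): ",
         paste(missing, collapse = ", "))
  vals <- as.matrix(df[, feature_names()])
  new_feature_matrix(vals, df[, meta_cols], normalization = normalization)
}
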