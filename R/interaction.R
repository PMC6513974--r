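#' Remove subject effects by per-subject centering
#'
#' Fixed-effect subject model: subtracts each subject's mean, isolating the
#' within-subject response from inter-subject variation. For balanced data
#' this equals the residuals of a linear model with per-subject intercepts.
#'
#' @param values Numeric vector.
#' @param subject_ids Subject identifier per value (>= 2 subjects).
#' @return Residuals; they sum to zero within every subject.
#' @export
residualize_subject <- function(values, subject_ids) {
  if (length(values) < 2) stop("need at least 2 values")
  if (length(unique(subject_ids)) < 2) stop("need at least 2 subjects")
  mu <- tapply(values, subject_ids, mean)
  values - as.numeric(mu[as.character(subject_ids)])
}

#' Normality-gated two-sample comparison
#'
#' Tests the pooled residuals for normality with a Kolmogorov-Smirnov test
#' against a normal with estimated (sample) parameters; if normality is
#' rejected at `alpha_ks`, a Wilcoxon rank-sum test compares the two
#' conditions, otherwise a two-sample t-test does. Degenerate zero-variance
#' input yields p = 1 with `test_used = "none"`.
#'
#' @param resid_b,resid_t4 Residual samples of the two conditions (each
#'   size >= 5).
#' @param alpha_ks Normality-gate level (default 0.05).
#' @return List with `p_value` and `test_used` (`"t"` or `"wilcoxon"`).
#' @export
compare_conditions <- function(resid_b, resid_t4, alpha_ks = 0.05) {
  if (length(resid_b) < 5 || length(resid_t4) < 5)
    stop("both samples must have at least 5 values")
  pooled <- c(resid_b, resid_t4)
  if (stats::sd(pooled) == 0)
    return(list(p_value = 1, test_used = "none"))
  ks_p <- suppressWarnings(
    stats::ks.test(pooled, "pnorm", mean(pooled), stats::sd(pooled))$p.value)
  if (is.na(ks_p) || ks_p < alpha_ks) {
    p <- suppressWarnings(
      stats::wilcox.test(resid_b, resid_t4, exact = FALSE)$p.value)
    list(p_value = p, test_used = "wilcoxon")
  } else {
    p <- stats::t.test(resid_b, resid_t4)$p.value
    list(p_value = p, test_used = "t")
  }
}

#' Cohen's d
#'
#' Standardized mean difference `(mean(b) - mean(a)) / pooled SD` with
#' (n-1)-weighted pooling; positive when the second sample exceeds the
#' first. Zero pooled SD yields 0.
#'
#' @param a,b Numeric samples (each >= 2 values).
#' @return The effect size.
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("both samples need >= 2 values")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) return(0)
  (mean(b) - mean(a)) / sqrt(sp2)
}

#' Category symbol for an interaction cell
#'
#' Maps a p-value and signed Cohen's d to the arrow notation: `"-"` when
#' p >= 0.05 or |d| < 0.2; otherwise one, two, or three arrows for
#' 0.2 <= |d| < 0.5, 0.5 <= |d| < 0.8, and |d| >= 0.8, pointing up when the
#' pain-tolerance mean exceeds baseline (d > 0) and down otherwise.
#'
#' @param p Two-sided p-value.
#' @param d Signed Cohen's d (tolerance minus baseline convention).
#' @param alpha Significance gate (default 0.05).
#' @return One of `"-"`, `"up"`, `"up2"`, `"up3"`, `"down"`, `"down2"`,
#'   `"down3"` — ASCII category codes; see [category_symbol()] for the
#'   arrow glyphs.
#' @export
categorize_effect <- function(p, d, alpha = 0.05) {
  if (is.na(p) || p >= alpha || abs(d) < 0.2) return("-")
  band <- if (abs(d) < 0.5) 1 else if (abs(d) < 0.8) 2 else 3
  dir <- if (d > 0) "up" else "down"
  paste0(dir, if (band > 1) band else "")
}

#' Arrow glyph of a category code
#'
#' @param category Code from [categorize_effect()].
#' @return UTF-8 arrow string (`"↑↑"` etc.), `"-"`, or `"na"`.
#' @export
category_symbol <- function(category) {
  map <- c("-" = "-", na = "na",
           up = "↑", up2 = "↑↑", up3 = "↑↑↑",
           down = "↓", down2 = "↓↓",
           down3 = "↓↓↓")
  unname(map[category])
}

#' Baseline-vs-tolerance interaction table
#'
#' For every feature (optionally a subset): removes subject effects from the
#' raw feature values across all available levels, compares baseline and
#' pain-tolerance residuals with the normality-gated test, computes signed
#' Cohen's d on the residuals (tolerance minus baseline), and assigns the
#' arrow category. Modality-feature combinations outside the registry are
#' reported as `"na"` in the wide table.
#'
#' @param matrix A `pf_feature_matrix` (raw values) containing both `B` and
#'   `T4` rows.
#' @param features Feature names to analyze (default: all 155).
#' @param alpha_ks Normality-gate level.
#' @return A `pf_interaction`: list with `summary` (long data.frame:
#'   `feature`, `p_value`, `d`, `direction`, `category`, `test_used`) and
#'   `table` (wide data.frame, base features x modalities, cells = category
#'   codes or `"na"`).
#' @export
interaction_table <- function(matrix, features = feature_names(),
                              alpha_ks = 0.05) {
  stopifnot(inherits(matrix, "pf_feature_matrix"))
  lv <- matrix$meta$level
  if (!all(c("B", "T4") %in% lv))
    stop("matrix must contain both B and T4 rows")
  res <- lapply(features, function(f) {
    vals <- matrix$values[, f]
    r <- residualize_subject(vals, matrix$meta$subject_id)
    rb <- r[lv == "B"]
    rt <- r[lv == "T4"]
    cmp <- compare_conditions(rb, rt, alpha_ks)
    d <- cohens_d(rb, rt)
    cat <- categorize_effect(cmp$p_value, d)
    data.frame(feature = f, p_value = cmp$p_value, d = d,
               direction = if (cat == "-") "none" else
                 if (d > 0) "T4_greater" else "B_greater",
               category = cat, test_used = cmp$test_used,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, res)

  reg <- feature_registry()
  base <- base_feature_table()
  chans <- c("zEMG", "cEMG", "tEMG", "SCL", "ECG")
  wide <- data.frame(feature = base$abbrev, stringsAsFactors = FALSE)
  for (ch in chans) {
    col <- rep("na", nrow(base))
    for (i in seq_len(nrow(base))) {
      nm <- reg$name[reg$channel == ch & reg$abbrev == base$abbrev[i]]
      if (length(nm) == 1 && nm %in% summary$feature)
        col[i] <- summary$category[summary$feature == nm]
    }
    wide[[ch]] <- col
  }
  structure(list(summary = summary, table = wide), class = "pf_interaction")
}

#' @export
print.pf_interaction <- function(x, ...) {
  sig <- sum(x$summary$category != "-")
  cat(sprintf("<pf_interaction> %d features tested, %d non-null categories\n",
              nrow(x$summary), sig))
  invisible(x)
}

#' Write interaction outputs to CSV
#'
#' The wide table (rows = base features, columns = modalities, cells =
#' category codes) and the long summary with numeric p, d, and test used.
#'
#' @param interaction A `pf_interaction`.
#' @param wide_path,long_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_interaction_csv <- function(interaction, wide_path, long_path) {
  utils::write.csv(interaction$table, wide_path, row.names = FALSE)
  utils::write.csv(interaction$summary, long_path, row.names = FALSE)
  invisible(c(wide_path, long_path))
}
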