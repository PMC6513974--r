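#' Classification problems
#'
#' The four pain-level classification problems: pain threshold (B vs T1),
#' pain tolerance (B vs T4), three-class (B vs T1 vs T4), and five-class
#' (all levels).
#'
#' @param name One of `"pain_threshold"`, `"pain_tolerance"`,
#'   `"three_class"`, `"five_class"`.
#' @return List with `name` and `levels`.
#' @export
classification_problem <- function(name = c("pain_threshold", "pain_tolerance",
                                            "three_class", "five_class")) {
  name <- match.arg(name)
  levels <- switch(name,
    pain_threshold = c("B", "T1"),
    pain_tolerance = c("B", "T4"),
    three_class = c("B", "T1", "T4"),
    five_class = pain_levels())
  list(name = name, levels = levels)
}

#' Stratified epoch splits
#'
#' Generates `n_epochs` independent splits of the trials belonging to a
#' classification problem, each stratified by subject and pain level: a
#' one-quarter hold-out (75% outer train / 25% test) and a 3-fold partition
#' of the train rows, one fold serving as the wrapper validation set (chosen
#' per epoch from the epoch's seed) and the other two as the
#' feature-selection train set. On the 20-trial-per-level roster this gives,
#' per subject per level, 15 train / 5 test rows and 10 FS-train / 5
#' validation rows; other counts use nearest-integer stratification.
#'
#' @param meta A `pf_feature_matrix` or a data.frame with `subject_id` and
#'   `level` columns (one row per trial).
#' @param problem From [classification_problem()].
#' @param n_epochs Number of epochs (study default 100).
#' @param seed Integer seed.
#' @return List of `pf_split` objects: each has `epoch_id`, `rows` (row
#'   indices belonging to the problem), `train`, `test`, `folds` (list of 3),
#'   `fs_train`, `val`, and `val_fold`.
#' @export
make_epoch_splits <- function(meta, problem, n_epochs = 100, seed = 1) {
  if (inherits(meta, "pf_feature_matrix")) meta <- meta$meta
  if (!all(problem$levels %in% meta$level))
    stop("problem levels absent from the roster: ",
         paste(setdiff(problem$levels, meta$level), collapse = ", "))
  rows <- which(meta$level %in% problem$levels)
  strata <- split(rows, list(meta$subject_id[rows], meta$level[rows]),
                  drop = TRUE)
  seeds <- .derive_seeds(seed, n_epochs)
  lapply(seq_len(n_epochs), function(e) {
    .with_seed(seeds[e], {
      train <- integer(0); test <- integer(0)
      folds <- list(integer(0), integer(0), integer(0))
      for (st in strata) {
        st <- sample(st)
        n_test <- max(1L, round(length(st) / 4))
        test <- c(test, st[seq_len(n_test)])
        tr <- st[-seq_len(n_test)]
        train <- c(train, tr)
        fold_of <- rep(1:3, length.out = length(tr))
        for (k in 1:3) folds[[k]] <- c(folds[[k]], tr[fold_of == k])
      }
      val_fold <- sample.int(3, 1)
      structure(list(epoch_id = e, rows = rows,
                     train = sort(train), test = sort(test),
                     folds = lapply(folds, sort),
                     fs_train = sort(unlist(folds[-val_fold])),
                     val = sort(folds[[val_fold]]),
                     val_fold = val_fold, seed = seeds[e]),
                class = "pf_split")
    })
  })
}

#' One-way ANOVA F statistic
#'
#' Classical between-/within-group mean-square ratio. Zero within-class
#' variance with unequal group means yields `Inf` (such a feature sorts
#' first in the ranking); zero variance with equal means yields 0.
#'
#' @param values Numeric vector.
#' @param labels Class labels (>= 2 classes, each with >= 2 values).
#' @return The F value.
#' @export
anova_f <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("need at least 2 classes")
  if (any(table(labels) < 2)) stop("each class needs at least 2 values")
  .anova_f_matrix(matrix(values, ncol = 1), labels)[1]
}

# vectorized one-way F over the columns of X
.anova_f_matrix <- function(X, y) {
  y <- droplevels(as.factor(y))
  n <- nrow(X)
  k <- nlevels(y)
  gm <- colMeans(X)
  ssb <- numeric(ncol(X))
  ssw <- numeric(ncol(X))
  for (lv in levels(y)) {
    idx <- y == lv
    m <- colMeans(X[idx, , drop = FALSE])
    ssb <- ssb + sum(idx) * (m - gm)^2
    ssw <- ssw + colSums(sweep(X[idx, , drop = FALSE], 2, m)^2)
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  as.numeric(f)
}

#' Univariate feature ranking by mean ANOVA F
#'
#' Computes, per epoch, the one-way F value of every feature on that epoch's
#' feature-selection train rows, then ranks features by descending mean F
#' across epochs (ties broken by registry order).
#'
#' @param matrix A `pf_feature_matrix`.
#' @param labels Class labels per row (default: the matrix's pain levels).
#' @param splits From [make_epoch_splits()].
#' @return A `pf_ranking`: list with `features` (names in rank order),
#'   `mean_f`, and `per_epoch` (epochs x features matrix of F values).
#' @export
ufs_rank <- function(matrix, labels = matrix$meta$level, splits) {
  X <- matrix$values
  per_epoch <- t(vapply(splits, function(sp)
    .anova_f_matrix(X[sp$fs_train, , drop = FALSE], labels[sp$fs_train]),
    numeric(ncol(X))))
  colnames(per_epoch) <- colnames(X)
  mean_f <- colMeans(per_epoch)
  ord <- order(-mean_f, seq_along(mean_f))
  structure(list(features = colnames(X)[ord], mean_f = mean_f[ord],
                 per_epoch = per_epoch),
            class = "pf_ranking")
}

#' @export
print.pf_ranking <- function(x, n = 10, ...) {
  cat("<pf_ranking> top features by mean F:\n")
  print(utils::head(data.frame(feature = x$features, mean_f = x$mean_f,
                               row.names = NULL), n))
  invisible(x)
}

# Gaussian naive Bayes sufficient statistics: per-class means, variances
# (floored), log priors
.gnb_fit <- function(X, y) {
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  mu <- s2 <- matrix(0, length(classes), ncol(X))
  lp <- numeric(length(classes))
  for (i in seq_along(classes)) {
    idx <- y == classes[i]
    Xi <- X[idx, , drop = FALSE]
    mu[i, ] <- colMeans(Xi)
    s2[i, ] <- pmax(apply(Xi, 2, stats::var), 1e-9)
    lp[i] <- log(sum(idx) / nrow(X))
  }
  list(classes = classes, mu = mu, s2 = s2, logprior = lp)
}

# per-class per-feature Gaussian log densities for every row of X:
# list over classes of (nrow(X) x ncol(X)) matrices
.gnb_logdens <- function(fit, X) {
  lapply(seq_along(fit$classes), function(i) {
    mu <- fit$mu[i, ]; s2 <- fit$s2[i, ]
    d <- sweep(X, 2, mu)
    -0.5 * sweep(d^2, 2, s2, "/") - 0.5 * log(2 * pi) -
      0.5 * matrix(log(s2), nrow(X), ncol(X), byrow = TRUE)
  })
}

# predicted class indices given summed log-likelihood columns per class
.gnb_argmax <- function(scores) {
  # scores: list over classes of equal-dim matrices (or vectors)
  best <- scores[[1]]
  cls <- array(1L, dim = dim(as.matrix(best)))
  for (i in seq_along(scores)[-1]) {
    upd <- scores[[i]] > best
    best[upd] <- scores[[i]][upd]
    cls[upd] <- i
  }
  cls
}

#' Sequential forward selection for one epoch
#'
#' Greedy wrapper selection with a Gaussian Naive Bayes objective: at each
#' iteration every remaining feature is evaluated jointly with the current
#' set, the classifier being trained on the epoch's FS-train rows and scored
#' by accuracy on the validation fold; the best-scoring feature is added
#' (ties broken by registry order). Runs to `max_iters` so the full
#' iteration curve is available for post-hoc analysis.
#'
#' @param matrix A `pf_feature_matrix`.
#' @param labels Class labels per row (default: pain levels).
#' @param split One `pf_split`.
#' @param max_iters Number of features to select.
#' @return List with `features` (selection order) and `accuracy`
#'   (validation accuracy after each addition).
#' @export
sfs_epoch <- function(matrix, labels = matrix$meta$level, split,
                      max_iters = 10) {
  nm <- colnames(matrix$values)
  max_iters <- min(max_iters, length(nm))
  Xtr <- matrix$values[split$fs_train, , drop = FALSE]
  ytr <- labels[split$fs_train]
  Xva <- matrix$values[split$val, , drop = FALSE]
  yva <- labels[split$val]
  # z-score on the FS-train rows (no leakage; the wrapper objective is
  # invariant to the affine map but the contract keeps features on one scale)
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xtr <- sweep(sweep(Xtr, 2, ctr), 2, scl, "/")
  Xva <- sweep(sweep(Xva, 2, ctr), 2, scl, "/")

  fit <- .gnb_fit(Xtr, ytr)
  L <- .gnb_logdens(fit, Xva)  # list over classes: n_val x n_feat
  yva_idx <- match(yva, fit$classes)
  selected <- integer(0)
  acc <- numeric(max_iters)
  base <- lapply(fit$logprior, function(p) rep(p, nrow(Xva)))
  remaining <- rep(TRUE, length(nm))
  for (it in seq_len(max_iters)) {
    cand_scores <- lapply(seq_along(L), function(i) base[[i]] + L[[i]])
    pred <- .gnb_argmax(cand_scores)  # n_val x n_feat class indices
    accs <- colMeans(pred == yva_idx)
    accs[!remaining] <- -Inf
    best <- which.max(accs)  # first max = registry order tie-break
    selected <- c(selected, best)
    remaining[best] <- FALSE
    acc[it] <- accs[best]
    base <- lapply(seq_along(L), function(i) base[[i]] + L[[i]][, best])
  }
  list(features = nm[selected], accuracy = acc)
}

#' Majority vote over per-epoch SFS selections
#'
#' Tabulates, per iteration, how often each feature was chosen at that
#' iteration across epochs, together with the mean validation accuracy of
#' the epochs that chose it. The consensus set is the top-voted feature per
#' iteration (ties broken by registry order).
#'
#' @param per_epoch List of [sfs_epoch()] results.
#' @param n_iters Number of iterations to tabulate (default: the shortest
#'   selection length).
#' @return A `pf_vote_table`: list with `table` (data.frame `iteration`,
#'   `feature`, `votes`, `vote_pct`, `mean_accuracy`) and `consensus`
#'   (character vector, one feature per iteration).
#' @export
sfs_vote <- function(per_epoch, n_iters = NULL) {
  lens <- vapply(per_epoch, function(e) length(e$features), integer(1))
  if (is.null(n_iters)) n_iters <- min(lens)
  if (any(lens < n_iters)) stop("some epochs ran fewer iterations than n_iters")
  n_ep <- length(per_epoch)
  reg_order <- feature_names()
  rows <- list()
  consensus <- character(n_iters)
  for (it in seq_len(n_iters)) {
    chosen <- vapply(per_epoch, function(e) e$features[it], character(1))
    accs <- vapply(per_epoch, function(e) e$accuracy[it], numeric(1))
    tab <- table(chosen)
    df <- data.frame(iteration = it, feature = names(tab),
                     votes = as.integer(tab),
                     vote_pct = 100 * as.integer(tab) / n_ep,
                     mean_accuracy = vapply(names(tab), function(f)
                       mean(accs[chosen == f]), numeric(1)),
                     row.names = NULL, stringsAsFactors = FALSE)
    df <- df[order(-df$votes, match(df$feature, reg_order)), ]
    rows[[it]] <- df
    consensus[it] <- df$feature[1]
  }
  structure(list(table = do.call(rbind, rows), consensus = consensus,
                 n_epochs = n_ep),
            class = "pf_vote_table")
}

#' Distinct consensus feature set from per-epoch SFS selections
#'
#' Builds a set of distinct features by repeated plurality voting: at each
#' step every epoch votes for the first feature in its own selection order
#' that is not yet in the set, and the top-voted feature is added (ties
#' broken by registry order). Unlike the per-iteration winners of
#' [sfs_vote()] — which can repeat a feature when epochs disagree on
#' ordering — this aggregation always yields `n_set` distinct features and
#' is the set used for recovery analyses and accuracy curves.
#'
#' @param per_epoch List of [sfs_epoch()] results.
#' @param n_set Number of features to aggregate.
#' @return Character vector of up to `n_set` distinct feature names.
#' @export
sfs_consensus_set <- function(per_epoch, n_set) {
  S <- character(0)
  regord <- feature_names()
  for (i in seq_len(n_set)) {
    votes <- vapply(per_epoch, function(e) {
      left <- setdiff(e$features, S)
      if (length(left)) left[1] else NA_character_
    }, character(1))
    tab <- table(votes[!is.na(votes)])
    if (!length(tab)) break
    cand <- names(tab)[tab == max(tab)]
    S <- c(S, cand[order(match(cand, regord))][1])
  }
  S
}

#' @export
print.pf_vote_table <- function(x, ...) {
  cat(sprintf("<pf_vote_table> %d epochs; consensus: %s\n", x$n_epochs,
              paste(x$consensus, collapse = ", ")))
  invisible(x)
}

#' Accuracy curve of an ordered feature set
#'
#' For each n, trains a linear soft-margin SVM (C = 1, one-against-one for
#' multi-class) on each epoch's outer train rows using the top-n features
#' (z-scored with statistics fit on the train rows) and scores accuracy on
#' the held-out test rows.
#'
#' @param matrix A `pf_feature_matrix`.
#' @param labels Class labels per row (default: pain levels).
#' @param ordered_features Feature names in inclusion order (from
#'   [ufs_rank()] or the [sfs_vote()] consensus).
#' @param splits From [make_epoch_splits()].
#' @param n_max Largest feature count to evaluate (default: all of
#'   `ordered_features`).
#' @param cost SVM regularization parameter (default 1).
#' @return A `pf_curve`: list with `n`, `mean`, `sd` (accuracy across
#'   epochs), and `per_epoch` (epochs x n matrix).
#' @export
evaluate_curve <- function(matrix, labels = matrix$meta$level,
                           ordered_features, splits,
                           n_max = length(ordered_features), cost = 1) {
  n_max <- min(n_max, length(ordered_features))
  acc <- matrix(NA_real_, length(splits), n_max)
  for (e in seq_along(splits)) {
    sp <- splits[[e]]
    Xtr <- matrix$values[sp$train, ordered_features, drop = FALSE]
    Xte <- matrix$values[sp$test, ordered_features, drop = FALSE]
    ytr <- factor(labels[sp$train])
    yte <- factor(labels[sp$test], levels = levels(ytr))
    ctr <- colMeans(Xtr)
    scl <- apply(Xtr, 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, ctr), 2, scl, "/")
    Xte <- sweep(sweep(Xte, 2, ctr), 2, scl, "/")
    for (n in seq_len(n_max)) {
      fit <- e1071::svm(Xtr[, seq_len(n), drop = FALSE], ytr,
                        kernel = "linear", cost = cost, scale = FALSE)
      pred <- stats::predict(fit, Xte[, seq_len(n), drop = FALSE])
      acc[e, n] <- mean(pred == yte)
    }
  }
  structure(list(n = seq_len(n_max), mean = colMeans(acc),
                 sd = apply(acc, 2, stats::sd), per_epoch = acc),
            class = "pf_curve")
}

#' @export
print.pf_curve <- function(x, ...) {
  cat(sprintf("<pf_curve> accuracy over %d feature counts (%d epochs); max %.1f%% at n = %d\n",
              length(x$n), nrow(x$per_epoch), 100 * max(x$mean),
              x$n[which.max(x$mean)]))
  invisible(x)
}

#' @export
plot.pf_curve <- function(x, ...) {
  graphics::plot(x$n, 100 * x$mean, type = "b", pch = 16,
                 xlab = "number of features", ylab = "accuracy (%)", ...)
  graphics::arrows(x$n, 100 * (x$mean - x$sd), x$n, 100 * (x$mean + x$sd),
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Local and global maxima of an accuracy curve
#'
#' The local maximum is the smallest feature count n whose step to n+1
#' yields neither a significant difference (paired t-test of the per-epoch
#' accuracies at n and n+1, at level `alpha`) nor a substantive one (mean
#' gain of at least `floor_pp` percentage points); a curve improving to its
#' end yields n = N. The global maximum is the rounded mean over epochs of
#' the first feature count attaining each epoch's maximum accuracy. The
#' local maximum is capped at the global one so `local <= global` always
#' holds.
#'
#' @param curve A `pf_curve` with per-epoch accuracies.
#' @param alpha Significance level for the step test (default 0.05).
#' @param floor_pp Substantive floor in accuracy percentage points
#'   (default 0.5).
#' @return List with `local_max_n` and `global_max_n`.
#' @export
curve_maxima <- function(curve, alpha = 0.05, floor_pp = 0.5) {
  acc <- curve$per_epoch
  N <- ncol(acc)
  per_epoch_arg <- apply(acc, 1, which.max)
  global_max_n <- max(1L, round(mean(per_epoch_arg)))
  local <- N
  for (n in seq_len(N - 1)) {
    d <- acc[, n + 1] - acc[, n]
    p <- if (stats::sd(d) > 0)
      stats::t.test(d)$p.value
    else NA_real_
    significant <- !is.na(p) && p < alpha
    substantive <- mean(d) >= floor_pp / 100
    if (!significant && !substantive) { local <- n; break }
  }
  list(local_max_n = min(local, global_max_n), global_max_n = global_max_n)
}

#' Run the full selection protocol for one problem
#'
#' Convenience wrapper: builds epoch splits, runs UFS ranking and per-epoch
#' SFS with majority voting, and evaluates SVM accuracy curves for both
#' orderings.
#'
#' @param matrix A `pf_feature_matrix`.
#' @param problem From [classification_problem()] (or its name).
#' @param n_epochs Number of epochs.
#' @param seed Integer seed.
#' @param sfs_iters SFS iterations per epoch.
#' @param n_max Curve length for the UFS ordering.
#' @return List with `splits`, `ranking`, `sfs` (per-epoch results), `vote`,
#'   `ufs_curve`, `sfs_curve`, and `maxima` (per curve).
#' @export
run_selection <- function(matrix, problem, n_epochs = 100, seed = 1,
                          sfs_iters = 8, n_max = 20) {
  if (is.character(problem)) problem <- classification_problem(problem)
  splits <- make_epoch_splits(matrix, problem, n_epochs, seed)
  labels <- matrix$meta$level
  ranking <- ufs_rank(matrix, labels, splits)
  sfs <- lapply(splits, function(sp) sfs_epoch(matrix, labels, sp, sfs_iters))
  vote <- sfs_vote(sfs)
  consensus <- sfs_consensus_set(sfs, sfs_iters)
  ufs_curve <- evaluate_curve(matrix, labels, ranking$features, splits,
                              n_max = n_max)
  sfs_curve <- evaluate_curve(matrix, labels, consensus, splits)
  list(problem = problem, splits = splits, ranking = ranking, sfs = sfs,
       vote = vote, consensus = consensus, ufs_curve = ufs_curve,
       sfs_curve = sfs_curve,
       maxima = list(ufs = curve_maxima(ufs_curve),
                     sfs = curve_maxima(sfs_curve)))
}
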