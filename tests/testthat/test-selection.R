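test_that("classification problems carry the stated level sets", {
  expect_equal(classification_problem("pain_threshold")$levels, c("B", "T1"))
  expect_equal(classification_problem("pain_tolerance")$levels, c("B", "T4"))
  expect_equal(classification_problem("three_class")$levels, c("B", "T1", "T4"))
  expect_equal(classification_problem("five_class")$levels, pain_levels())
  expect_error(classification_problem("six_class"))
})

test_that("epoch splits stratify exactly on the 20-trial roster", {
  fm <- synth_feature_matrix(4, 20, seed = 5)
  prob <- classification_problem("pain_tolerance")
  splits <- make_epoch_splits(fm, prob, n_epochs = 5, seed = 2)
  m <- fm$meta
  for (sp in splits) {
    expect_equal(length(sp$train) / (length(sp$train) + length(sp$test)), 0.75)
    expect_setequal(c(sp$train, sp$test), sp$rows)
    expect_length(intersect(sp$train, sp$test), 0)
    # per subject per level: 15 train / 5 test, 10 FS-train / 5 validation
    for (cnt in list(table(m$subject_id[sp$train], m$level[sp$train])))
      expect_true(all(cnt[, c("B", "T4")] == 15))
    expect_true(all(table(m$subject_id[sp$test], m$level[sp$test]) == 5))
    expect_true(all(table(m$subject_id[sp$fs_train], m$level[sp$fs_train]) == 10))
    expect_true(all(table(m$subject_id[sp$val], m$level[sp$val]) == 5))
    expect_setequal(c(sp$fs_train, sp$val), sp$train)
    # only problem levels appear
    expect_true(all(m$level[sp$rows] %in% prob$levels))
  }
  # determinism
  splits2 <- make_epoch_splits(fm, prob, n_epochs = 5, seed = 2)
  expect_identical(splits, splits2)
  expect_error(make_epoch_splits(fm$meta[fm$meta$level == "B", ], prob, 2, 1),
               "absent")
})

test_that("one-way F matches hand arithmetic and the lm oracle", {
  expect_equal(anova_f(c(1, 2, 3, 4), c("a", "a", "b", "b")), 8)
  set.seed(6)
  for (i in 1:20) {
    v <- rnorm(30)
    g <- sample(rep(c("a", "b", "c"), 10))
    expect_equal(anova_f(v, g), oracle_anova_f(v, g), tolerance = 1e-9)
  }
  expect_error(anova_f(1:4, rep("a", 4)), "2 classes")
  expect_error(anova_f(1:3, c("a", "a", "b")), "2 values")
  # zero within-class variance with distinct means sorts first
  expect_equal(anova_f(c(1, 1, 2, 2), c("a", "a", "b", "b")), Inf)
})

test_that("the F test holds its nominal level under the null", {
  set.seed(7)
  hits <- 0
  n_rep <- 1000
  for (i in seq_len(n_rep)) {
    v <- rnorm(40)
    g <- rep(c("a", "b"), 20)
    f <- anova_f(v, g)
    p <- pf(f, 1, 38, lower.tail = FALSE)
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.035)
  expect_lte(hits / n_rep, 0.065)
})

test_that("UFS ranks an injected effect first and is redundancy-blind", {
  fm <- synth_feature_matrix(10, 10, informative = c(sSDSD = 1.5), seed = 8)
  splits <- make_epoch_splits(fm, classification_problem("pain_tolerance"),
                              n_epochs = 5, seed = 3)
  rk <- ufs_rank(fm, splits = splits)
  expect_equal(rk$features[1], "sSDSD")
  expect_true(all(diff(rk$mean_f) <= 0))

  # duplicated top column occupies ranks 1-2
  fm2 <- fm
  fm2$values[, "zMAV"] <- fm2$values[, "sSDSD"]
  rk2 <- ufs_rank(fm2, splits = splits)
  expect_setequal(rk2$features[1:2], c("zMAV", "sSDSD"))

  # an all-null matrix yields top mean F consistent with the null spread
  fm0 <- synth_feature_matrix(10, 10, seed = 9)
  rk0 <- ufs_rank(fm0, splits = splits)
  # top-of-155 null F stays below a Bonferroni-style null envelope
  expect_lt(rk0$mean_f[1], qf(1 - 0.001 / 155, 1, 90))
  expect_gt(rk0$mean_f[1], 1)
})

test_that("SFS picks a perfect separator first and ignores duplicates", {
  fm <- synth_feature_matrix(6, 12, seed = 10)
  lv <- fm$meta$level
  # make cRMS a perfect separator for B vs T4
  fm$values[, "cRMS"] <- ifelse(lv == "T4", 10, 0) + rnorm(nrow(fm$values), 0, 0.1)
  splits <- make_epoch_splits(fm, classification_problem("pain_tolerance"),
                              n_epochs = 3, seed = 4)
  res <- sfs_epoch(fm, split = splits[[1]], max_iters = 4)
  expect_equal(res$features[1], "cRMS")
  expect_equal(res$accuracy[1], 1)

  # an exact duplicate of the selected feature never increases the objective
  fm2 <- fm
  fm2$values[, "zMAV"] <- fm2$values[, "cRMS"]
  res2 <- sfs_epoch(fm2, split = splits[[1]], max_iters = 4)
  first <- res2$features[1]
  dup <- if (first == "cRMS") "zMAV" else "cRMS"
  idx <- match(dup, res2$features)
  if (!is.na(idx)) expect_lte(res2$accuracy[idx], res2$accuracy[idx - 1])

  # seed-fixed determinism
  res3 <- sfs_epoch(fm, split = splits[[1]], max_iters = 4)
  expect_identical(res, res3)
})

test_that("the SFS wrapper objective agrees with an independent Naive Bayes", {
  fm <- synth_feature_matrix(6, 12, informative = c(cP2P = 1, sApEn = 0.8),
                             seed = 11)
  sp <- make_epoch_splits(fm, classification_problem("pain_tolerance"),
                          n_epochs = 1, seed = 5)[[1]]
  res <- sfs_epoch(fm, split = sp, max_iters = 2)
  labels <- fm$meta$level
  # recompute the reported validation accuracies with e1071::naiveBayes
  for (k in 1:2) {
    feats <- res$features[1:k]
    Xtr <- fm$values[sp$fs_train, feats, drop = FALSE]
    Xva <- fm$values[sp$val, feats, drop = FALSE]
    ctr <- colMeans(Xtr); scl <- apply(Xtr, 2, sd)
    Xtr <- sweep(sweep(Xtr, 2, ctr), 2, scl, "/")
    Xva <- sweep(sweep(Xva, 2, ctr), 2, scl, "/")
    nb <- e1071::naiveBayes(Xtr, factor(labels[sp$fs_train]))
    acc <- mean(predict(nb, Xva) == labels[sp$val])
    expect_equal(res$accuracy[k], acc)
  }
})

test_that("vote tables partition epochs and reward unanimity", {
  sel <- list(list(features = c("cP2P", "zCC"), accuracy = c(0.8, 0.9)),
              list(features = c("cP2P", "sApEn"), accuracy = c(0.7, 0.8)),
              list(features = c("cP2P", "zCC"), accuracy = c(0.9, 0.9)))
  v <- sfs_vote(sel)
  t1 <- v$table[v$table$iteration == 1, ]
  expect_equal(t1$vote_pct, 100)
  expect_equal(t1$feature, "cP2P")
  t2 <- v$table[v$table$iteration == 2, ]
  expect_equal(sum(t2$votes), 3)
  expect_equal(v$consensus[2], "zCC")
  # distinct aggregation never repeats a feature
  s <- sfs_consensus_set(sel, 2)
  expect_equal(s, c("cP2P", "zCC"))
  expect_error(sfs_vote(sel, n_iters = 5), "fewer")
})

test_that("SFS consensus recovers designated informative features", {
  inf <- c(cP2P = 1, cShannonEn = 1, sSDSD = 1, zCC = 1, hslopeRR = 1)
  recovered <- vapply(1:3, function(s) {
    fm <- synth_feature_matrix(20, 20, informative = inf, seed = 40 + s)
    splits <- make_epoch_splits(fm, classification_problem("pain_tolerance"),
                                n_epochs = 20, seed = 140 + s)
    sfs <- lapply(splits, function(sp) sfs_epoch(fm, split = sp, max_iters = 6))
    length(intersect(sfs_consensus_set(sfs, 5), names(inf)))
  }, numeric(1))
  expect_gte(mean(recovered) / 5, 0.8)
})

test_that("SVM accuracy curves behave at the separable and chance extremes", {
  # separable two-class problem: perfect accuracy from one feature
  fm <- synth_feature_matrix(6, 8, seed = 12)
  lv <- fm$meta$level
  fm$values[, "cP2P"] <- ifelse(lv == "T4", 5, -5) + rnorm(nrow(fm$values), 0, 0.1)
  splits <- make_epoch_splits(fm, classification_problem("pain_tolerance"),
                              n_epochs = 3, seed = 6)
  cur <- evaluate_curve(fm, ordered_features = c("cP2P", "zMAV"), splits = splits)
  expect_equal(cur$mean[1], 1)

  # pure-noise features: two balanced classes stay near 50%
  fm0 <- synth_feature_matrix(10, 12, seed = 13, subject_sd = 0)
  splits0 <- make_epoch_splits(fm0, classification_problem("pain_tolerance"),
                               n_epochs = 8, seed = 7)
  cur0 <- evaluate_curve(fm0, ordered_features = feature_names()[1:3],
                         splits = splits0)
  expect_gt(mean(cur0$mean), 0.45)
  expect_lt(mean(cur0$mean), 0.55)

  # five balanced classes stay near 20%
  splits5 <- make_epoch_splits(fm0, classification_problem("five_class"),
                               n_epochs = 8, seed = 8)
  cur5 <- evaluate_curve(fm0, ordered_features = feature_names()[1:3],
                         splits = splits5)
  expect_gt(mean(cur5$mean), 0.13)
  expect_lt(mean(cur5$mean), 0.27)
})

test_that("curve maxima identify plateaus and respect local <= global", {
  # constructed plateau after n = 3
  set.seed(14)
  base <- c(0.60, 0.70, 0.80, 0.801, 0.799, 0.8)
  per_epoch <- t(replicate(20, base + rnorm(6, 0, 0.002)))
  curve <- structure(list(n = 1:6, mean = colMeans(per_epoch),
                          sd = apply(per_epoch, 2, sd),
                          per_epoch = per_epoch), class = "pf_curve")
  mx <- curve_maxima(curve)
  expect_equal(mx$local_max_n, 3)
  expect_lte(mx$local_max_n, mx$global_max_n)

  # strictly increasing curve: local = global = N
  inc <- t(replicate(10, c(0.5, 0.6, 0.7, 0.8)))
  curve2 <- structure(list(n = 1:4, mean = colMeans(inc),
                           sd = apply(inc, 2, sd), per_epoch = inc),
                      class = "pf_curve")
  mx2 <- curve_maxima(curve2)
  expect_equal(mx2$local_max_n, 4)
  expect_equal(mx2$global_max_n, 4)

  # random curves always satisfy the ordering invariant
  set.seed(15)
  for (i in 1:10) {
    pe <- matrix(runif(60, 0.4, 0.9), 10, 6)
    cv <- structure(list(n = 1:6, mean = colMeans(pe),
                         sd = apply(pe, 2, sd), per_epoch = pe),
                    class = "pf_curve")
    m <- curve_maxima(cv)
    expect_lte(m$local_max_n, m$global_max_n)
    expect_gte(m$local_max_n, 1)
  }
})

test_that("no test row leaks into selection statistics", {
  fm <- synth_feature_matrix(4, 8, seed = 16)
  sp <- make_epoch_splits(fm, classification_problem("pain_tolerance"),
                          n_epochs = 1, seed = 9)[[1]]
  # perturbing test rows changes neither F values nor SFS selections
  fm_pert <- fm
  fm_pert$values[sp$test, ] <- fm_pert$values[sp$test, ] + 100
  rk1 <- ufs_rank(fm, splits = list(sp))
  rk2 <- ufs_rank(fm_pert, splits = list(sp))
  expect_identical(rk1$features, rk2$features)
  expect_equal(rk1$mean_f, rk2$mean_f)
  s1 <- sfs_epoch(fm, split = sp, max_iters = 3)
  s2 <- sfs_epoch(fm_pert, split = sp, max_iters = 3)
  expect_identical(s1, s2)
})
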