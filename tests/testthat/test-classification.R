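test_that("oversampling balances classes to the target and keeps every source row", {
  set.seed(1)
  X <- matrix(stats::rnorm(83 * 5), 83, 5)
  y <- factor(rep(c("UM", "control"), c(37, 46)))
  os <- oversample_balance(X, y, n_target = 200, seed = 3)
  expect_equal(as.integer(table(os$y)), c(200L, 200L))
  # every original row appears at least once; no foreign rows appear
  for (cl in levels(y)) {
    src <- X[y == cl, , drop = FALSE]
    out <- os$X[os$y == cl, , drop = FALSE]
    expect_true(all(apply(src, 1, function(r)
      any(colSums(abs(t(out) - r)) == 0))))
    expect_true(all(apply(out, 1, function(r)
      any(colSums(abs(t(src) - r)) == 0))))
  }
  # a class already at the target is returned unchanged up to row order
  X2 <- matrix(1:28, 14, 2)
  y2 <- factor(rep(c("a", "b"), c(10, 4)))
  os2 <- oversample_balance(X2, y2, n_target = 10, seed = 1)
  expect_equal(os2$X[os2$y == "a", ][order(os2$X[os2$y == "a", 1]), ],
               X2[order(X2[, 1]), ][1:10, ])
  expect_error(oversample_balance(X2, y2, n_target = 5, seed = 1),
               "configuration error")
  expect_error(oversample_balance(X2, factor(rep("a", 14), levels = c("a", "z")),
                                  20, 1), "empty class")
})

test_that("training noise has the configured moments and is reproducible", {
  X <- matrix(0, 400, 250)
  expect_identical(add_noise(X, sd = 0, seed = 1), X)
  N <- add_noise(X, sd = 0.25, seed = 2)
  expect_equal(stats::sd(N - X), 0.25, tolerance = 0.01)
  expect_equal(mean(N - X), 0, tolerance = 0.005)
  expect_identical(N, add_noise(X, sd = 0.25, seed = 2))
  expect_false(identical(N, add_noise(X, sd = 0.25, seed = 3)))
})

test_that("ROC/AUC handles separation, ties, and agrees with rank and pROC oracles", {
  # perfect separation
  ba <- bootstrap_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE),
                      n_boot = 25, seed = 1)
  expect_equal(as.numeric(ba), c(1, 0), ignore_attr = TRUE)
  # all-tied scores: every resample is 0.5
  bt <- bootstrap_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5), n_boot = 10,
                      seed = 2)
  expect_equal(as.numeric(bt), c(0.5, 0), ignore_attr = TRUE)
  # trapezoid AUC equals the Mann-Whitney rank statistic, including ties
  set.seed(7)
  for (i in 1:10) {
    scores <- round(stats::runif(40), 2)     # rounding forces ties
    truth <- stats::runif(40) < 0.45
    if (!any(truth) || all(truth)) next
    roc <- roc_curve(scores, truth)
    auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
    expect_equal(auc, rank_auc(scores, truth), tolerance = 1e-12)
    expect_equal(auc,
                 as.numeric(pROC::auc(pROC::roc(
                   response = truth, predictor = scores,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap AUC matches the rank oracle under shared resample indices", {
  set.seed(11)
  scores <- stats::runif(40)
  truth <- stats::runif(40) < 0.5
  n_boot <- 25
  ba <- bootstrap_auc(scores, truth, n_boot = n_boot, seed = 99)
  # replay the documented resampling scheme and apply the rank oracle
  set.seed(99)
  oracle <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(40, 40, replace = TRUE)
      if (any(truth[idx]) && !all(truth[idx])) break
    }
    oracle[b] <- rank_auc(scores[idx], truth[idx])
  }
  expect_equal(attr(ba, "auc_boot"), oracle, tolerance = 1e-12)
  expect_equal(ba[["auc_mean"]], mean(oracle), tolerance = 1e-12)
  expect_equal(ba[["auc_sd"]], stats::sd(oracle), tolerance = 1e-12)
  expect_error(bootstrap_auc(scores, rep(TRUE, 40)), "both classes")
})

test_that("LOOCV separates separable clusters perfectly and is deterministic", {
  d <- separable_xy(n1 = 12, n2 = 12, p = 20, margin = 10, seed = 5)
  cfg <- pipeline_config(oversample_n = 50, n_trees = 100)
  r <- loocv_classify(d$X, d$y, cfg, seed = 4)
  expect_equal(r$accuracy, 1)
  expect_equal(r$auc_mean, 1)
  expect_equal(r$auc_sd, 0)
  expect_equal(nrow(r$probabilities), 24)            # one row per sample
  expect_equal(unname(rowSums(r$probabilities)), rep(1, 24), tolerance = 1e-9)
  expect_identical(as.character(r$predictions),
                   as.character(r$class_labels[apply(r$probabilities, 1,
                                                     which.max)]))
  r2 <- loocv_classify(d$X, d$y, cfg, seed = 4)
  expect_identical(r$probabilities, r2$probabilities)
  expect_error(loocv_classify(d$X, factor(rep("UM", 24)), cfg),
               "configuration error")
})

test_that("fold grouping keeps technical replicates out of their source's training fold", {
  set.seed(21)
  X <- matrix(stats::rnorm(20 * 10), 20, 10)
  rownames(X) <- sprintf("s%02d", 1:20)
  y <- factor(rep(c("UM", "control"), each = 10))
  cfg <- pipeline_config(oversample_n = 30, n_trees = 60)
  base <- loocv_classify(X, y, cfg, seed = 9)
  # append an exact copy of sample 1 sharing its fold group: sample 1's
  # held-out probability must be unchanged because the copy never enters
  # its training fold
  X2 <- rbind(X, s_copy = X[1, ])
  y2 <- factor(c(as.character(y), as.character(y[1])), levels = levels(y))
  r2 <- loocv_classify(X2, y2, cfg, seed = 9,
                       fold_groups = c(rownames(X), rownames(X)[1]))
  expect_equal(r2$probabilities[1, ], base$probabilities[1, ],
               tolerance = 1e-12)
})

test_that("per-class report metrics equal brute-force confusion counts", {
  d <- separable_xy(8, 8, 10, margin = 0, seed = 3)   # unseparable: mixed confusion
  cfg <- pipeline_config(oversample_n = 20, n_trees = 50)
  r <- loocv_classify(d$X, d$y, cfg, seed = 2)
  rep_tab <- classification_report(r)
  for (cl in r$class_labels) {
    tp <- sum(r$predictions == cl & r$truth == cl)
    fp <- sum(r$predictions == cl & r$truth != cl)
    fn <- sum(r$predictions != cl & r$truth == cl)
    row <- rep_tab[rep_tab$class == cl, ]
    expect_equal(row$precision, if (tp + fp == 0) 0 else tp / (tp + fp))
    expect_equal(row$recall, tp / (tp + fn))
    p <- row$precision; rc <- row$recall
    expect_equal(row$f1, if (p + rc == 0) 0 else 2 * p * rc / (p + rc))
  }
  expect_equal(attr(rep_tab, "accuracy"), mean(r$predictions == r$truth))
  # a never-predicted class takes the zero conventions
  fake <- r
  fake$per_class <- umetab:::per_class_metrics(
    factor(c("a", "a", "b"), levels = c("a", "b")),
    factor(c("a", "a", "a"), levels = c("a", "b")), c("a", "b"))
  expect_equal(fake$per_class$b[["precision"]], 0)
  expect_equal(fake$per_class$b[["f1"]], 0)
})

test_that("repeated subsampling reduces to plain LOOCV at frac 1 and varies draws otherwise", {
  d <- separable_xy(8, 8, 12, margin = 10, seed = 6)
  cfg1 <- pipeline_config(master_seed = 5, oversample_n = 20, n_trees = 50,
                          n_repeats = 1, subsample_frac = 1)
  rs <- repeated_subsample_cv(d$X, d$y, cfg1)
  plain <- loocv_classify(d$X, d$y, cfg1,
                          seed = derive_seed(cfg1$master_seed, "repeat", 1))
  expect_identical(rs$per_repeat[[1]]$probabilities, plain$probabilities)
  cfg2 <- pipeline_config(master_seed = 5, oversample_n = 20, n_trees = 50,
                          n_repeats = 3, subsample_frac = 0.5)
  rs2 <- repeated_subsample_cv(d$X, d$y, cfg2)
  expect_length(rs2$per_repeat, 3)
  expect_false(identical(rs2$sampled_ids[[1]], rs2$sampled_ids[[2]]))
  expect_true(all(vapply(rs2$per_repeat, function(r) r$auc_mean, 1) >= 0.95))
  expect_error(repeated_subsample_cv(d$X, d$y,
                                     pipeline_config(subsample_frac = 0.1)),
               "configuration error")
})
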