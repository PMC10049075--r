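# helper: a log1 table with given abundance matrix
log1_table <- function(ab, ids = sprintf("F%03d", seq_len(nrow(ab)))) {
  rownames(ab) <- NULL
  ft <- feature_table(ids, seq_len(nrow(ab)), seq_len(nrow(ab)),
                      "positive", matrix(0, nrow(ab), ncol(ab),
                                         dimnames = dimnames(ab)))
  ft$abundances <- ab
  ft$transform_state <- "log1"
  rownames(ft$abundances) <- ids
  ft
}

test_that("standard PCs reproduce a brute-force eigendecomposition", {
  set.seed(12)
  n_s <- 24
  ab <- matrix(stats::rnorm(8 * n_s, 10, 1), 8, n_s,
               dimnames = list(NULL, sprintf("S%02d", 1:n_s)))
  ids <- c(sprintf("IS_%02d", 1:6), "F001", "F002")
  ft <- log1_table(ab, ids)
  st <- standard_set(sprintf("IS_%02d", 1:6))
  model <- fit_standard_pcs(ft, st)
  # oracle: eigenvectors of the sample covariance of the samples x standards
  X <- scale(t(ab[1:6, ]), center = TRUE, scale = FALSE)
  e <- eigen(stats::cov(X), symmetric = TRUE)
  for (j in 1:2) {
    oracle <- X %*% e$vectors[, j]
    i <- which.max(abs(oracle))
    if (oracle[i] < 0) oracle <- -oracle
    expect_equal(unname(model$pc_scores[, j]), as.numeric(oracle),
                 tolerance = 1e-8)
  }
  expect_lt(abs(sum(model$pc_scores[, 1] * model$pc_scores[, 2])), 1e-6)
})

test_that("rank-1 standards give PC1 proportional to the profile and a null PC2", {
  n_s <- 20
  profile <- sin(seq(0, 2 * pi, length.out = n_s))
  ab <- rbind(10 + profile, 11 + profile, matrix(5, 2, n_s))
  colnames(ab) <- sprintf("S%02d", 1:n_s)
  ft <- log1_table(ab, c("IS_01", "IS_02", "F001", "F002"))
  model <- fit_standard_pcs(ft, standard_set(c("IS_01", "IS_02")))
  cor1 <- stats::cor(model$pc_scores[, 1], profile)
  expect_equal(abs(cor1), 1, tolerance = 1e-10)
  expect_lt(max(abs(model$pc_scores[, 2])), 1e-8)
})

test_that("constant standards are degenerate: zero scores, warning, identity normalization", {
  ab <- rbind(matrix(10, 2, 6), matrix(stats::rnorm(12, 8), 2, 6))
  colnames(ab) <- sprintf("S%02d", 1:6)
  ft <- log1_table(ab, c("IS_01", "IS_02", "F001", "F002"))
  expect_warning(model <- fit_standard_pcs(ft, standard_set(c("IS_01", "IS_02"))),
                 "degenerate")
  expect_true(all(model$pc_scores == 0))
  out <- normalize_pc_regression(ft, model)
  expect_equal(out$table$abundances, ft$abundances)
})

test_that("PC scores are invariant to the ordering of internal standards", {
  co <- simulate_cohort(demo_sim_config(5))
  lg <- log_transform(co$pos)
  st <- co$standards
  st_rev <- standard_set(rev(st$internal), st$external)
  m1 <- fit_standard_pcs(lg, st)
  m2 <- fit_standard_pcs(lg, st_rev)
  expect_equal(m1$pc_scores, m2$pc_scores, tolerance = 1e-10)
})

test_that("a feature that is an exact linear function of PC1 normalizes to its mean", {
  co <- simulate_cohort(demo_sim_config(6))
  lg <- log_transform(co$pos)
  model <- fit_standard_pcs(lg, co$standards)
  lin <- 9 + 0.8 * model$pc_scores[, 1]
  lg$abundances[which(lg$feature_ids == "P_F0001"), ] <- lin
  out <- normalize_pc_regression(lg, model)
  row <- out$table$abundances[which(lg$feature_ids == "P_F0001"), ]
  expect_equal(unname(row), rep(mean(lin), length(lin)), tolerance = 1e-6)
})

test_that("the ridge fit reduces to least squares at negligible penalty", {
  set.seed(33)
  n <- 40
  scores <- cbind(PC1 = stats::rnorm(n, 0, 3), PC2 = stats::rnorm(n, 0, 1.5))
  y <- 5 + 0.7 * scores[, 1] - 0.4 * scores[, 2] + stats::rnorm(n, 0, 0.05)
  ab <- rbind(y, matrix(stats::rnorm(2 * n, 10), 2, n))
  colnames(ab) <- sprintf("S%02d", 1:n)
  ft <- log1_table(ab, c("F001", "IS_01", "IS_02"))
  model <- list(sample_ids = colnames(ab), internal_ids = c("IS_01", "IS_02"),
                pc_scores = scores, degenerate = FALSE)
  class(model) <- "normalization_model"
  out <- normalize_pc_regression(ft, model, nonzero_frac = 0.5)
  ols <- stats::lm(y ~ scores)
  expect_equal(unname(out$table$abundances[1, ]),
               unname(stats::resid(ols) + mean(y)), tolerance = 1e-3)
})

test_that("ineligible features pass through bitwise unchanged", {
  co <- simulate_cohort(demo_sim_config(7))
  lg <- log_transform(co$pos)
  # force one feature below the 75% nonzero eligibility bar
  j <- which(lg$feature_ids == "P_F0002")
  n <- ncol(lg$abundances)
  lg$abundances[j, seq_len(ceiling(0.4 * n))] <- 0
  model <- fit_standard_pcs(lg, co$standards)
  out <- normalize_pc_regression(lg, model)
  expect_false(out$model$fitted_flag[j])
  expect_identical(out$table$abundances[j, ], lg$abundances[j, ])
  expect_true(all(is.na(out$model$per_feature_coefficients[j, ])))
  # mismatched samples are rejected
  sub <- subset_features(lg, samples = 1:10)
  expect_error(normalize_pc_regression(sub, model), "schema error")
})

test_that("outlier samples are excluded from the fit but still corrected", {
  set.seed(44)
  n <- 30
  scores <- cbind(PC1 = stats::rnorm(n, 0, 2), PC2 = stats::rnorm(n))
  y <- 10 + 0.5 * scores[, 1] + stats::rnorm(n, 0, 0.05)
  y[1] <- 30                     # gross outlier, |Z| far beyond 3
  ab <- rbind(y, matrix(stats::rnorm(2 * n, 10), 2, n))
  colnames(ab) <- sprintf("S%02d", 1:n)
  ft <- log1_table(ab, c("F001", "IS_01", "IS_02"))
  model <- structure(list(sample_ids = colnames(ab),
                          internal_ids = c("IS_01", "IS_02"),
                          pc_scores = scores, degenerate = FALSE),
                     class = "normalization_model")
  out <- normalize_pc_regression(ft, model)
  expect_true("S01" %in% out$model$excluded_samples[["F001"]])
  # the outlier is corrected with the coefficients fitted without it
  co <- out$model$per_feature_coefficients["F001", ]
  expect_equal(co[["b1"]], 0.5, tolerance = 0.05)
  expect_equal(out$table$abundances[1, 1],
               unname(y[1] - (co[[1]] + co[[2]] * scores[1, 1] +
                              co[[3]] * scores[1, 2]) + mean(y)),
               tolerance = 1e-8)
})

test_that("QC-based metrics behave at the edges", {
  co <- simulate_cohort(demo_sim_config(8))
  lg <- log_transform(co$pos)
  meta <- co$meta
  # duplicated QC profiles give correlation exactly 1
  qc_ids <- meta$sample_id[meta$role == "qc"]
  lg2 <- lg
  for (q in qc_ids[-1]) lg2$abundances[, q] <- lg2$abundances[, qc_ids[1]]
  met <- compute_norm_metrics(lg2, meta, seed = 2)
  expect_equal(met$qc_correlation, 1, tolerance = 1e-12)
  # a single batch reports wtr and batch score as absent, not zero
  disc <- meta$sample_id[meta$batch == "discovery"]
  sub <- subset_features(lg, samples = disc)
  met1 <- compute_norm_metrics(sub, meta[meta$batch == "discovery", ], seed = 2)
  expect_true(is.na(met1$wtr))
  expect_true(is.na(met1$batch_prediction_score))
  expect_false(is.na(met1$qc_correlation))
})

test_that("batch prediction score tracks injected batch separation", {
  # two batches drawn from one distribution: wtr near 1, score near chance
  ft <- rand_table(60, 40, seed = 13, state = "log1")
  meta <- mk_meta(colnames(ft$abundances),
                  group = "control",
                  batch = rep(c("discovery", "replication"), each = 20))
  met0 <- compute_norm_metrics(ft, meta, seed = 3)
  expect_gt(met0$wtr, 0.9)
  expect_lt(met0$batch_prediction_score, 0.75)
  # a large injected offset makes batch nearly perfectly predictable
  pert <- inject_batch_effect(ft, meta, sd = 2, seed = 5)
  met2 <- compute_norm_metrics(pert, meta, seed = 3)
  expect_gte(met2$batch_prediction_score, 0.9)
  expect_lt(met2$wtr, met0$wtr)
})
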