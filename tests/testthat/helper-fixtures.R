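# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

# random feature table + minimal matching metadata
rand_table <- function(n_feat = 20, n_samp = 8, seed = 1, state = "raw",
                       ion_mode = "positive", zero_frac = 0) {
  set.seed(seed)
  ab <- matrix(exp(stats::rnorm(n_feat * n_samp, 8, 2)), n_feat, n_samp)
  if (zero_frac > 0)
    ab[stats::runif(length(ab)) < zero_frac] <- 0
  colnames(ab) <- sprintf("S%03d", seq_len(n_samp))
  ft <- feature_table(sprintf("F%04d", seq_len(n_feat)),
                      mz = stats::runif(n_feat, 70, 1200),
                      rt = stats::runif(n_feat, 30, 900),
                      ion_mode = ion_mode, abundances = ab,
                      transform_state = "raw")
  if (state == "log1") ft <- log_transform(ft)
  if (state == "z") ft <- z_transform(log_transform(ft))
  ft
}

mk_meta <- function(ids, group = "UM", batch = "discovery", role = "study",
                    subclass = NULL, ltd = NULL) {
  n <- length(ids)
  group <- rep_len(group, n)
  if (is.null(subclass))
    subclass <- ifelse(group == "control", "control", "BAP1")
  if (is.null(ltd))
    ltd <- ifelse(group == "UM", 10, NA_real_)
  sample_metadata(data.frame(
    sample_id = ids, group = group, subclass = rep_len(subclass, n),
    batch = rep_len(batch, n), role = rep_len(role, n),
    ltd = ltd, stringsAsFactors = FALSE))
}

# Mann-Whitney rank AUC with 0.5 credit for ties: the independent oracle
# for the trapezoidal ROC implementation
rank_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  r <- rank(scores)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# hand-stepped Benjamini-Hochberg
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# clearly separable two-class data: clusters margin noise-sds apart
separable_xy <- function(n1 = 10, n2 = 10, p = 20, margin = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n1 * p), n1, p),
             matrix(stats::rnorm(n2 * p, mean = margin / sqrt(p)), n2, p))
  rownames(X) <- sprintf("s%03d", seq_len(n1 + n2))
  list(X = X, y = factor(rep(c("control", "UM"), c(n1, n2))))
}

# balanced-batch positive-control cohort for normalization recovery:
# identical group composition in both batches so the only batch-associated
# signal is the technical offset; share_exact standards; no dropout so every
# feature is eligible
stress_sim_config <- function(seed) {
  simulation_config(
    n_discovery = c(control = 20L, BAP1 = 15L, SF3B1 = 10L, EIF1AX = 10L),
    n_replication = c(control = 20L, BAP1 = 15L, SF3B1 = 10L, EIF1AX = 10L),
    batch_effect_sd = 1, dropout_rate = 0, share_exact = TRUE,
    n_qc = 4L, n_replicates = 0L, seed = seed)
}

# cohort with no group signal anywhere
null_sim_config <- function(seed, ...) {
  simulation_config(effect_size = 0, subclass_effect = 0,
                    ltd_feature_corr = 0, seed = seed, ...)
}

# scaled-down cohort for determinism / permutation-null runs
demo_sim_config <- function(seed) {
  simulation_config(
    n_discovery = c(control = 16L, BAP1 = 10L, SF3B1 = 6L, EIF1AX = 6L),
    n_replication = c(control = 0L, BAP1 = 6L, SF3B1 = 5L, EIF1AX = 3L),
    n_features = 60L, n_informative = 15L, n_qc = 4L, n_replicates = 1L,
    seed = seed)
}

# log -> filter -> joint PC-regression normalization -> z; the screening
# path used by the calibration checks
normalized_mode <- function(cohort, mode = "pos", cfg = pipeline_config()) {
  lg <- log_transform(cohort[[mode]])
  thr <- pooled_detection_threshold(lg, cfg$pooled_percentile)
  filt <- filter_features(lg, thr, cfg$min_samples_above, cohort$standards)
  model <- fit_standard_pcs(filt, cohort$standards)
  nr <- normalize_pc_regression(filt, model, cfg$nonzero_frac, cfg$z_outlier)
  z_transform(nr$table)
}
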