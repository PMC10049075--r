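#' Simulation configuration for synthetic cohorts
#'
#' Defines a two-batch, four-group case-control cohort with the statistical
#' structure the analysis assumes: log-normal feature abundances,
#' multiplicative (log-additive) batch effects shared in distribution with
#' the spiked standards, group effects on an informative feature subset,
#' below-detection dropout, pooled QC injections and technical replicates.
#'
#' Default group sizes follow the study cohort this pipeline was designed
#' around: discovery batch 37 BAP1 + 16 SF3B1 + 15 EIF1AX cases and 46
#' controls; replication batch 19 BAP1 + 17 SF3B1 + 9 EIF1AX cases. Ten
#' internal and seven external standards are spiked into every sample.
#'
#' @param n_discovery,n_replication named integer vectors with entries
#'   \code{control}, \code{BAP1}, \code{SF3B1}, \code{EIF1AX}.
#' @param n_features number of non-standard features per ion mode.
#' @param n_informative number of features carrying the case/control shift.
#' @param effect_size log-scale mean shift of informative features in UM
#'   samples (so Cohen's d = effect_size / sigma).
#' @param subclass_effect additional log-scale shift separating the BAP1 /
#'   SF3B1 / EIF1AX subclasses (0 = subclasses indistinguishable, the
#'   null structure reported for real cohorts).
#' @param sigma per-feature biological + technical noise sd (log scale).
#' @param batch_effect_sd sd of the per-feature log-scale offset applied to
#'   replication-batch samples; standards draw offsets from the same
#'   distribution.
#' @param dropout_rate probability that a study-sample entry is set to 0
#'   (below detection); never applied to standards or pooled QC samples,
#'   which are spiked/pooled well above the detection limit.
#' @param n_qc number of pooled QC samples (split over batches).
#' @param n_replicates number of technical replicate samples.
#' @param n_internal,n_external number of spiked standards.
#' @param ltd_feature_corr target correlation between one designated feature
#'   and the longest tumor diameter over UM samples.
#' @param share_exact if TRUE, standards are measured with negligible noise
#'   so their leading principal components capture the batch structure
#'   exactly; the positive control for PC-regression normalization.
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @return A list of class \code{simulation_config}.
#' @export
simulation_config <- function(
    n_discovery = c(control = 46L, BAP1 = 37L, SF3B1 = 16L, EIF1AX = 15L),
    n_replication = c(control = 0L, BAP1 = 19L, SF3B1 = 17L, EIF1AX = 9L),
    n_features = 200L, n_informative = 40L,
    effect_size = 1.0, subclass_effect = 0, sigma = 0.5,
    batch_effect_sd = 0.5, dropout_rate = 0.10,
    n_qc = 6L, n_replicates = 2L,
    n_internal = 10L, n_external = 7L,
    ltd_feature_corr = 0.7, share_exact = FALSE, seed = 1L) {
  grp <- c("control", "BAP1", "SF3B1", "EIF1AX")
  stopifnot(all(grp %in% names(n_discovery)), all(grp %in% names(n_replication)),
            all(n_discovery >= 0), all(n_replication >= 0),
            n_informative <= n_features, dropout_rate >= 0, dropout_rate < 1,
            sigma > 0, abs(ltd_feature_corr) <= 1)
  if (n_internal < 2)
    stop("configuration error: need >= 2 internal standards")
  structure(list(n_discovery = n_discovery[grp], n_replication = n_replication[grp],
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, subclass_effect = subclass_effect,
                 sigma = sigma, batch_effect_sd = batch_effect_sd,
                 dropout_rate = dropout_rate, n_qc = as.integer(n_qc),
                 n_replicates = as.integer(n_replicates),
                 n_internal = as.integer(n_internal),
                 n_external = as.integer(n_external),
                 ltd_feature_corr = ltd_feature_corr,
                 share_exact = share_exact, seed = as.integer(seed)),
            class = "simulation_config")
}

subclass_shift <- function(subclass) {
  # ordered by metastatic risk: BAP1 high, SF3B1 intermediate, EIF1AX low
  unname(c(BAP1 = 1, SF3B1 = 0, EIF1AX = -1, control = 0)[subclass])
}

#' Simulate a two-batch case-control metabolomics cohort
#'
#' Generative model on the log scale, per feature j and sample i:
#' \deqn{y_{ij} = \mu_j + b_j 1[batch_i = replication]
#'   + \delta_j 1[group_i = UM] + s_j shift(subclass_i) + \epsilon_{ij}}
#' with \eqn{\epsilon_{ij} \sim N(0, \sigma^2)}; raw abundance is
#' \eqn{e^{y_{ij}}}, zeroed with probability \code{dropout_rate} (never for
#' standards). Standards carry no group signal (\eqn{\delta_j = s_j = 0})
#' but draw batch offsets from the same distribution as the features, so the
#' technical structure is shared. QC samples are noisy replicates of the
#' pooled mean profile. One designated feature per mode correlates with the
#' longest tumor diameter at the configured level.
#'
#' @param cfg a \code{\link{simulation_config}}.
#' @return A list with elements \code{pos} and \code{neg}
#'   (raw-state \code{feature_table}s over the same samples), \code{meta}
#'   (a \code{sample_metadata}) and \code{standards} (a \code{standard_set}
#'   whose ids appear in both tables). Attributes on each table record the
#'   informative feature ids, the drawn batch offsets and the
#'   ltd-correlated feature id.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  meta <- simulate_metadata(cfg)
  out <- list()
  for (mode in c("positive", "negative")) {
    prefix <- if (mode == "positive") "P" else "N"
    out[[mode]] <- simulate_mode_table(cfg, meta, mode, prefix)
  }
  standards <- standard_set(sprintf("IS_%02d", seq_len(cfg$n_internal)),
                            sprintf("ES_%02d", seq_len(cfg$n_external)))
  list(pos = out$positive, neg = out$negative, meta = meta,
       standards = standards)
}

simulate_metadata <- function(cfg) {
  rows <- list()
  mk <- function(n, group, subclass, batch, idx0) {
    if (n == 0) return(NULL)
    ids <- sprintf("%s_%s_%03d", substr(batch, 1, 1), subclass, idx0 + seq_len(n))
    um <- group == "UM"
    data.frame(
      sample_id = ids, group = group, subclass = subclass,
      primary_driver = if (um) sample(c("GNAQ", "GNA11"), n, replace = TRUE)
                       else rep("missing", n),
      batch = batch, role = "study",
      storage_time = if (um) round(stats::runif(n, 0, 20), 1)
                     else round(stats::runif(n, 3, 5), 1),
      age = round(if (um) stats::rnorm(n, 63, 10) else stats::rnorm(n, 74, 7)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      ltd = if (um) round(stats::runif(n, 5, 20), 1) else NA_real_,
      metastasis = if (um) sample(c("yes", "no", "unknown"), n, replace = TRUE,
                                  prob = subclass_meta_prob(subclass))
                   else "no",
      stringsAsFactors = FALSE)
  }
  for (batch in c("discovery", "replication")) {
    counts <- if (batch == "discovery") cfg$n_discovery else cfg$n_replication
    for (g in names(counts)) {
      grp <- if (g == "control") "control" else "UM"
      rows[[paste(batch, g)]] <- mk(counts[[g]], grp, g, batch, 0L)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  # pooled QC injections, alternating over batches
  if (cfg$n_qc > 0) {
    qb <- rep(c("discovery", "replication"), length.out = cfg$n_qc)
    df <- rbind(df, data.frame(
      sample_id = sprintf("QC_%02d", seq_len(cfg$n_qc)), group = NA,
      subclass = NA, primary_driver = NA, batch = qb, role = "qc",
      storage_time = NA_real_, age = NA_real_, sex = NA, ltd = NA_real_,
      metastasis = NA, stringsAsFactors = FALSE))
  }
  if (cfg$n_replicates > 0) {
    study_ids <- df$sample_id[df$role == "study"]
    src <- sample(study_ids, cfg$n_replicates)
    rep_rows <- df[match(src, df$sample_id), ]
    rep_rows$sample_id <- sprintf("REP_%02d", seq_len(cfg$n_replicates))
    rep_rows$role <- paste0("replicate_of:", src)
    df <- rbind(df, rep_rows)
  }
  rownames(df) <- NULL
  sample_metadata(df)
}

subclass_meta_prob <- function(subclass) {
  switch(subclass,
         BAP1 = c(0.6, 0.3, 0.1), SF3B1 = c(0.3, 0.6, 0.1),
         c(0.05, 0.85, 0.1))
}

simulate_mode_table <- function(cfg, meta, mode, prefix) {
  n_std <- cfg$n_internal + cfg$n_external
  feat_ids <- c(sprintf("IS_%02d", seq_len(cfg$n_internal)),
                sprintf("ES_%02d", seq_len(cfg$n_external)),
                sprintf("%s_F%04d", prefix, seq_len(cfg$n_features)))
  n_feat <- length(feat_ids)
  is_std <- seq_len(n_feat) <= n_std
  study <- is_study_role(meta$role)
  n_samp <- nrow(meta)

  mu <- ifelse(is_std, stats::runif(n_feat, 10, 12), stats::runif(n_feat, 8, 14))
  b <- stats::rnorm(n_feat, 0, cfg$batch_effect_sd)      # shared distribution
  informative <- n_std + seq_len(cfg$n_informative)
  delta <- numeric(n_feat); delta[informative] <- cfg$effect_size
  s <- numeric(n_feat); s[informative] <- cfg$subclass_effect

  in_batch2 <- meta$batch == "replication"
  is_um <- !is.na(meta$group) & meta$group == "UM"
  shift <- ifelse(is.na(meta$subclass), 0, subclass_shift(meta$subclass))

  y <- matrix(0, n_feat, n_samp, dimnames = list(feat_ids, meta$sample_id))
  std_sd <- if (cfg$share_exact) 1e-3 else 0.1
  qc_idx <- which(meta$role == "qc")
  for (i in seq_len(n_samp)) {
    if (i %in% qc_idx) {
      m <- mu + b * in_batch2[i]
      y[, i] <- m + stats::rnorm(n_feat, 0, ifelse(is_std, std_sd, 0.15))
    } else {
      m <- mu + b * in_batch2[i] + delta * is_um[i] + s * shift[i]
      y[, i] <- m + stats::rnorm(n_feat, 0, ifelse(is_std, std_sd, cfg$sigma))
    }
  }
  # replicates: remeasure their source sample with small technical noise
  rep_idx <- grep("^replicate_of:", meta$role)
  for (i in rep_idx) {
    src <- sub("^replicate_of:", "", meta$role[i])
    y[, i] <- y[, match(src, meta$sample_id)] + stats::rnorm(n_feat, 0, 0.1)
  }
  # designated ltd-correlated feature: first non-informative feature
  ltd_j <- n_std + cfg$n_informative + 1L
  um_idx <- which(is_um & study)
  if (cfg$ltd_feature_corr != 0 && ltd_j <= n_feat && length(um_idx) >= 3) {
    r <- cfg$ltd_feature_corr
    z_ltd <- as.numeric(scale(meta$ltd[um_idx]))
    y[ltd_j, um_idx] <- mu[ltd_j] + b[ltd_j] * in_batch2[um_idx] +
      cfg$sigma * (r * z_ltd + sqrt(1 - r^2) * stats::rnorm(length(um_idx)))
  }
  raw <- exp(y)
  if (cfg$dropout_rate > 0) {
    drop <- matrix(stats::runif(n_feat * n_samp) < cfg$dropout_rate,
                   n_feat, n_samp)
    drop[is_std, ] <- FALSE      # standards spiked at fixed concentration
    drop[, qc_idx] <- FALSE      # pooled QC: everything well above detection
    raw[drop] <- 0
  }
  ft <- feature_table(feat_ids, mz = round(stats::runif(n_feat, 70, 1200), 4),
                      rt = round(stats::runif(n_feat, 30, 900), 1),
                      ion_mode = mode, abundances = raw,
                      transform_state = "raw")
  attr(ft, "informative_ids") <- feat_ids[informative]
  attr(ft, "batch_offsets") <- stats::setNames(b, feat_ids)
  attr(ft, "ltd_feature") <- if (ltd_j <= n_feat) feat_ids[ltd_j] else NA
  ft
}

#' Inject an additional batch effect into a log-transformed table
#'
#' Adds a per-feature offset \eqn{b_j \sim N(0, sd^2)} to every
#' replication-batch sample, standards included; a stress input for the
#' PC-regression normalization.
#'
#' @param ft \code{feature_table} in \code{log1} state.
#' @param meta matching \code{sample_metadata}.
#' @param sd offset standard deviation (log scale).
#' @param seed RNG seed.
#' @return The perturbed table; drawn offsets in attribute
#'   \code{"injected_offsets"}.
#' @export
inject_batch_effect <- function(ft, meta, sd, seed) {
  if (ft$transform_state != "log1")
    stop("state error: inject_batch_effect needs a log1-state table")
  check_sample_match(ft, meta)
  set.seed(seed)
  b <- stats::rnorm(length(ft$feature_ids), 0, sd)
  idx <- meta$batch[match(colnames(ft$abundances), meta$sample_id)] == "replication"
  out <- ft
  out$abundances[, idx] <- out$abundances[, idx] + b
  attr(out, "injected_offsets") <- stats::setNames(b, ft$feature_ids)
  out
}
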