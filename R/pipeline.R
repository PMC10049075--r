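#' Run the full analysis pipeline on a simulated cohort
#'
#' End-to-end demonstration run: simulate a two-batch cohort, then per ion
#' mode log-transform, apply the detection filter per batch, normalize each
#' batch by internal-standard PC regression, merge batches by feature
#' intersection, Z-transform, classify UM versus control with oversampled
#' noise-regularized random-forest LOOCV (bootstrap AUC), screen features
#' for differential abundance and tumor-size correlation, and embed the
#' samples. All artifacts are written under \code{out_dir} as TSV/JSON and
#' digested into a manifest, so a rerun with the same seeds reproduces
#' identical digests for every deterministic stage.
#'
#' @param sim_cfg a \code{\link{simulation_config}} describing the cohort.
#' @param cfg a \code{\link{pipeline_config}} with the protocol constants.
#' @param out_dir output directory (created if needed).
#' @param run_classification,run_embeddings,run_diffabund stage switches.
#' @param norm_scope \code{"per_batch"} (default): each batch is
#'   residualized against its own standards PCs before merging, so only
#'   within-batch technical variation is removed; \code{"joint"}: one model
#'   over all samples, whose leading PC also captures the between-batch
#'   offset and removes it.
#' @return A list of class \code{pipeline_run}: per-mode results
#'   (\code{filter_report}, \code{norm_metrics_before/after},
#'   \code{cv}, \code{diffabund}, \code{embedding}) and \code{manifest}.
#' @export
run_pipeline <- function(sim_cfg = simulation_config(),
                         cfg = pipeline_config(), out_dir = tempfile("umetab_run_"),
                         run_classification = TRUE, run_embeddings = TRUE,
                         run_diffabund = TRUE,
                         norm_scope = c("per_batch", "joint")) {
  norm_scope <- match.arg(norm_scope)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  cohort <- simulate_cohort(sim_cfg)
  meta <- cohort$meta
  standards <- cohort$standards
  std_path <- file.path(out_dir, "standards.json")
  write_standards(standards, std_path)
  stages$simulate <- digest_files(std_path)
  results <- list()
  for (mode in c("pos", "neg")) {
    ft_raw <- cohort[[mode]]
    tab_path <- file.path(out_dir, paste0(mode, "_raw.tsv"))
    write_feature_table(ft_raw, meta, tab_path)
    res <- analyze_mode(ft_raw, meta, standards, cfg,
                        run_classification, run_embeddings, run_diffabund,
                        norm_scope = norm_scope)
    res_path <- file.path(out_dir, paste0(mode, "_results.json"))
    jsonlite::write_json(summarize_mode(res), res_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    stages[[paste0("analyze_", mode)]] <-
      digest_files(c(tab_path, paste0(tab_path, ".meta.tsv"), res_path))
    results[[mode]] <- res
  }
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(config_hash = unname(digest_files(cfg_path)),
                   master_seed = cfg$master_seed,
                   sim_seed = sim_cfg$seed,
                   stages = stages,
                   version = as.character(utils::packageVersion("umetab")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest[setdiff(names(manifest), "timestamp")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(list(results = results, manifest = manifest, out_dir = out_dir,
                 meta = meta, standards = standards),
            class = "pipeline_run")
}

digest_files <- function(paths) {
  h <- tools::md5sum(paths)
  names(h) <- basename(paths)
  as.list(h)
}

# One ion mode: filter per batch, normalize (per batch or jointly), merge
# by feature intersection, z-transform, then classify/screen/embed.
analyze_mode <- function(ft_raw, meta, standards, cfg,
                         run_classification = TRUE, run_embeddings = TRUE,
                         run_diffabund = TRUE, norm_scope = "per_batch") {
  lg <- log_transform(ft_raw)
  batches <- list()
  filter_report <- list()
  norm_models <- list()
  for (b in c("discovery", "replication")) {
    ids <- meta$sample_id[meta$batch == b]
    ids <- intersect(colnames(lg$abundances), ids)
    if (length(ids) == 0) next
    sub <- subset_features(lg, samples = ids)
    thr <- pooled_detection_threshold(sub, cfg$pooled_percentile)
    filt <- filter_features(sub, thr, cfg$min_samples_above, standards)
    filter_report[[b]] <- list(n_features_in = length(sub$feature_ids),
                               threshold = as.numeric(thr),
                               n_features_out = length(filt$feature_ids))
    if (norm_scope == "per_batch") {
      model <- fit_standard_pcs(filt, standards)
      nr <- normalize_pc_regression(filt, model, cfg$nonzero_frac,
                                    cfg$z_outlier)
      batches[[b]] <- list(pre = filt, post = nr$table)
      norm_models[[b]] <- nr$model
    } else {
      batches[[b]] <- list(pre = filt)
    }
  }
  if (length(batches) == 2) {
    merged_pre <- merge_batches(batches$discovery$pre, batches$replication$pre)
  } else {
    merged_pre <- batches[[1]]$pre
  }
  if (norm_scope == "per_batch") {
    merged_post <- if (length(batches) == 2)
      merge_batches(batches$discovery$post, batches$replication$post)
    else batches[[1]]$post
  } else {
    model <- fit_standard_pcs(merged_pre, standards)
    nr <- normalize_pc_regression(merged_pre, model, cfg$nonzero_frac,
                                  cfg$z_outlier)
    merged_post <- nr$table
    norm_models$joint <- nr$model
  }
  meta_m <- meta[match(colnames(merged_post$abundances), meta$sample_id), ]
  metrics_before <- compute_norm_metrics(merged_pre, meta_m,
                                         seed = derive_seed(cfg$master_seed, "metrics0"))
  metrics_after <- compute_norm_metrics(merged_post, meta_m,
                                        seed = derive_seed(cfg$master_seed, "metrics1"))
  zt <- z_transform(merged_post)
  out <- list(ion_mode = ft_raw$ion_mode, filter_report = filter_report,
              norm_models = norm_models,
              norm_metrics_before = metrics_before,
              norm_metrics_after = metrics_after,
              table = zt)
  study <- classification_inputs(zt, meta_m)
  if (run_classification)
    out$cv <- loocv_classify(study$X, study$y, cfg,
                             seed = derive_seed(cfg$master_seed, "cv",
                                                ft_raw$ion_mode),
                             fold_groups = study$fold_groups)
  if (run_diffabund)
    out$diffabund <- diff_abundance(zt, meta_m, alpha = cfg$fdr_alpha)
  if (run_embeddings) {
    out$embedding <- pca_embedding(zt, k = 2)
    out$ellipses <- group_ellipses(out$embedding,
                                   meta_m$group[match(out$embedding$sample_ids,
                                                      meta_m$sample_id)])
  }
  out
}

# study-sample design matrix for classification; replicates share the fold
# group of their source sample so they never leak across the fold boundary
classification_inputs <- function(zt, meta, labels = "group") {
  meta <- meta[match(colnames(zt$abundances), meta$sample_id), ]
  rep_src <- sub("^replicate_of:", "", meta$role)
  usable <- is_study_role(meta$role) & !is.na(meta[[labels]])
  X <- t(zt$abundances[, usable, drop = FALSE])
  groups <- meta$sample_id[usable]
  list(X = X, y = factor(meta[[labels]][usable]), fold_groups = groups,
       sample_ids = meta$sample_id[usable])
}

summarize_mode <- function(res) {
  s <- list(ion_mode = res$ion_mode, filter = res$filter_report,
            norm_metrics_before = unclass(res$norm_metrics_before),
            norm_metrics_after = unclass(res$norm_metrics_after))
  if (!is.null(res$cv)) {
    s$classification <- list(
      accuracy = res$cv$accuracy,
      auc_mean = res$cv$auc_mean, auc_sd = res$cv$auc_sd,
      per_class = lapply(res$cv$per_class, as.list))
  }
  if (!is.null(res$diffabund)) {
    s$diffabund <- list(
      n_features = nrow(res$diffabund),
      n_joint = sum(res$diffabund$joint_flag),
      n_q_t_sig = sum(res$diffabund$q_t <= attr(res$diffabund, "alpha")))
  }
  s
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Render a human-readable run report
#'
#' One text document per run: per-mode filter counts, normalization
#' metrics before and after, the classification table with AUC +/- sd, and
#' the differential-abundance summary. Metrics whose preconditions failed
#' are shown as absent rather than zero.
#'
#' @param run a \code{pipeline_run}.
#' @return Character vector of report lines.
#' @export
render_report <- function(run) {
  stopifnot(inherits(run, "pipeline_run"))
  lines <- c(sprintf("umetab pipeline run (master seed %d)",
                     run$manifest$master_seed), "")
  for (mode in names(run$results)) {
    res <- run$results[[mode]]
    lines <- c(lines, sprintf("== %s ion mode ==", res$ion_mode))
    for (b in names(res$filter_report)) {
      fr <- res$filter_report[[b]]
      lines <- c(lines, sprintf(
        "  filter [%s]: %d -> %d features (threshold %.4f)",
        b, fr$n_features_in, fr$n_features_out, fr$threshold))
    }
    mb <- res$norm_metrics_before; ma <- res$norm_metrics_after
    lines <- c(lines,
      sprintf("  normalization: wtr %s -> %s; batch prediction %s -> %s; qc corr %s -> %s",
              fmt_na(mb$wtr), fmt_na(ma$wtr),
              fmt_na(mb$batch_prediction_score), fmt_na(ma$batch_prediction_score),
              fmt_na(mb$qc_correlation), fmt_na(ma$qc_correlation)))
    if (!is.null(res$cv)) {
      rep_tab <- classification_report(res$cv)
      lines <- c(lines, "  classification (UM vs control, LOOCV):")
      lines <- c(lines, sprintf("    %-10s precision %.2f  recall %.2f  f1 %.2f  (n=%d)",
                                rep_tab$class, rep_tab$precision,
                                rep_tab$recall, rep_tab$f1, rep_tab$support))
      lines <- c(lines, sprintf("    accuracy %.3f, AUC %.3f +/- %.3f",
                                res$cv$accuracy, res$cv$auc_mean, res$cv$auc_sd))
    }
    if (!is.null(res$diffabund)) {
      alpha <- attr(res$diffabund, "alpha")
      lines <- c(lines, sprintf(
        "  differential abundance: %d features, %d with q_t <= %.2f, %d jointly significant",
        nrow(res$diffabund), sum(res$diffabund$q_t <= alpha), alpha,
        sum(res$diffabund$joint_flag)))
    }
    lines <- c(lines, "")
  }
  lines
}
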