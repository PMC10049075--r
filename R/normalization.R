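#' Fit principal components of the internal standards
#'
#' The spiked internal standards measure per-sample technical variation
#' (injection volume, ionization efficiency, batch drift). Treating samples
#' as observations and the centered internal-standard rows as variables,
#' this computes the first two principal-component score vectors over
#' samples; they are the regressors the normalization removes from every
#' feature. Sign convention: the largest-magnitude entry of each score
#' vector is positive, so results are deterministic.
#'
#' @param ft \code{feature_table} in \code{log1} state with >= 3 samples.
#' @param standards \code{standard_set}; >= 2 internal standards must be in
#'   the table.
#' @return A \code{normalization_model} with elements \code{pc_scores}
#'   (n_samples x 2), \code{pc_loadings}, \code{explained_variance},
#'   \code{sample_ids}, \code{degenerate} (TRUE when the standards carry no
#'   variance, in which case the scores are all zero and a warning is
#'   raised).
#' @export
fit_standard_pcs <- function(ft, standards) {
  if (ft$transform_state != "log1")
    stop("state error: standards PCA operates on the log1 scale")
  int_ids <- intersect(standards$internal, ft$feature_ids)
  if (length(int_ids) < 2)
    stop("configuration error: need >= 2 internal standards in the table")
  if (ncol(ft$abundances) < 3)
    stop("configuration error: need >= 3 samples")
  S <- ft$abundances[match(int_ids, ft$feature_ids), , drop = FALSE]
  X <- t(S)                          # samples x standards
  X <- scale(X, center = TRUE, scale = FALSE)
  model <- list(sample_ids = colnames(ft$abundances), internal_ids = int_ids)
  if (all(abs(X) < 1e-12)) {
    warning("degenerate standards: no variance across samples; zero scores")
    model$pc_scores <- matrix(0, nrow(X), 2,
                              dimnames = list(rownames(X), c("PC1", "PC2")))
    model$pc_loadings <- matrix(0, length(int_ids), 2,
                                dimnames = list(int_ids, c("PC1", "PC2")))
    model$explained_variance <- c(0, 0)
    model$degenerate <- TRUE
    class(model) <- "normalization_model"
    return(model)
  }
  sv <- svd(X)
  k <- min(2L, ncol(sv$u))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  if (k < 2) {                       # pad a zero second component
    scores <- cbind(scores, 0)
    loadings <- cbind(loadings, 0)
  }
  for (j in 1:2) {                   # deterministic sign
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  dimnames(scores) <- list(rownames(X), c("PC1", "PC2"))
  dimnames(loadings) <- list(int_ids, c("PC1", "PC2"))
  ev <- sv$d^2 / sum(sv$d^2)
  model$pc_scores <- scores
  model$pc_loadings <- loadings
  model$explained_variance <- c(ev, 0, 0)[1:2]
  model$degenerate <- FALSE
  class(model) <- "normalization_model"
  model
}

#' @export
print.normalization_model <- function(x, ...) {
  cat(sprintf("normalization_model: %d internal standards, %d samples, PC1+PC2 explain %.1f%% of standard variance%s\n",
              length(x$internal_ids), length(x$sample_ids),
              100 * sum(x$explained_variance),
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

# Ridge fit of y on the two PC score columns; lambda chosen by generalized
# cross-validation over a grid that includes 0, so a negligible optimal
# penalty reduces to ordinary least squares.
ridge_pc_fit <- function(y, scores, lambda_grid = c(0, 10^seq(-4, 2, length.out = 13))) {
  df <- data.frame(y = y, PC1 = scores[, 1], PC2 = scores[, 2])
  if (stats::sd(df$PC1) < 1e-12 && stats::sd(df$PC2) < 1e-12)
    return(c(mean(y), 0, 0))
  if (stats::sd(df$PC2) < 1e-12) {
    fit <- MASS::lm.ridge(y ~ PC1, data = df, lambda = lambda_grid)
    co <- coef(fit)[which.min(fit$GCV), ]
    return(c(co[1], co[2], 0))
  }
  fit <- MASS::lm.ridge(y ~ PC1 + PC2, data = df, lambda = lambda_grid)
  unname(coef(fit)[which.min(fit$GCV), ])
}

#' Normalize features by regression on the standard PCs
#'
#' For every eligible feature (at least \code{nonzero_frac} of samples with
#' abundance above zero) the log abundance is regressed on the two internal-
#' standard principal components; samples with per-feature |Z| >
#' \code{z_outlier} are excluded from the fit but still corrected. Each
#' value is replaced by its residual plus the feature mean, so the technical
#' component expressible in the standards is removed while the feature's
#' location is preserved. Ineligible features pass through unchanged and
#' keep their log-transformed abundance.
#'
#' The regression is ridge-regularized with a data-driven (GCV) penalty; at
#' a negligible penalty it coincides with ordinary least squares.
#'
#' @param ft \code{feature_table} in \code{log1} state.
#' @param model \code{normalization_model} fitted on the same samples.
#' @param nonzero_frac eligibility fraction (default 0.75).
#' @param z_outlier |Z| cutoff for excluding samples from the fit.
#' @return A list: \code{table} (normalized \code{feature_table}, still
#'   \code{log1} state) and \code{model} completed with
#'   \code{per_feature_coefficients} and \code{excluded_samples}.
#' @export
normalize_pc_regression <- function(ft, model, nonzero_frac = 0.75,
                                    z_outlier = 3.0) {
  if (ft$transform_state != "log1")
    stop("state error: normalization operates on the log1 scale")
  if (!identical(colnames(ft$abundances), model$sample_ids))
    stop("schema error: model fitted on different samples than the table")
  X <- ft$abundances
  n <- ncol(X)
  scores <- model$pc_scores
  eligible <- rowSums(X > 0) >= ceiling(nonzero_frac * n)
  coefs <- matrix(NA_real_, nrow(X), 3,
                  dimnames = list(ft$feature_ids, c("intercept", "b1", "b2")))
  excluded <- vector("list", nrow(X)); names(excluded) <- ft$feature_ids
  out <- X
  degenerate <- isTRUE(model$degenerate)
  for (f in which(eligible)) {
    y <- X[f, ]
    if (degenerate) { coefs[f, ] <- c(mean(y), 0, 0); next }
    mu <- mean(y); s <- stats::sd(y)
    keep <- if (s > 0) abs((y - mu) / s) <= z_outlier else rep(TRUE, n)
    excluded[[f]] <- colnames(X)[!keep]
    if (sum(keep) < 4) keep <- rep(TRUE, n)   # too few points to drop any
    co <- ridge_pc_fit(y[keep], scores[keep, , drop = FALSE])
    coefs[f, ] <- co
    fitted_all <- co[1] + scores[, 1] * co[2] + scores[, 2] * co[3]
    out[f, ] <- y - fitted_all + mean(y)
  }
  model$per_feature_coefficients <- coefs
  model$fitted_flag <- eligible
  model$excluded_samples <- excluded[eligible]
  tab <- ft
  tab$abundances <- out
  list(table = tab, model = model)
}

#' Normalization performance metrics
#'
#' Four diagnostics of how well technical variation was removed:
#' \describe{
#'   \item{wtr}{within-batch / total variance ratio, averaged over
#'     features; approaches 1 when batch variation is gone.}
#'   \item{qc_correlation}{mean pairwise Pearson correlation of QC-sample
#'     profiles; high when technical noise is low.}
#'   \item{batch_prediction_score}{stratified 5-fold cross-validated
#'     balanced accuracy of a default random forest predicting the batch
#'     label from the features; near 0.5 when batches are
#'     indistinguishable.}
#'   \item{qc_prediction_score}{same classifier separating QC from study
#'     samples.}
#' }
#' Metrics whose preconditions fail (a single batch, fewer than 2 QC
#' samples) are reported as NA, never as 0.
#'
#' @param ft \code{feature_table} (log1 or z state).
#' @param meta matching \code{sample_metadata}.
#' @param seed integer seed for fold assignment and forests.
#' @return A list of class \code{normalization_metrics}.
#' @export
compute_norm_metrics <- function(ft, meta, seed = 1L) {
  check_sample_match(ft, meta)
  meta <- meta[match(colnames(ft$abundances), meta$sample_id), ]
  X <- t(ft$abundances)              # samples x features
  batch <- meta$batch
  role_qc <- meta$role == "qc"
  wtr <- NA_real_; batch_score <- NA_real_
  if (length(unique(batch)) >= 2) {
    wtr <- wtr_score(ft$abundances, batch)
    batch_score <- cv_balanced_accuracy(X, factor(batch), seed = derive_seed(seed, "batch"))
  }
  qc_corr <- NA_real_; qc_score <- NA_real_
  if (sum(role_qc) >= 2) {
    qc <- ft$abundances[, role_qc, drop = FALSE]
    cm <- stats::cor(qc)
    qc_corr <- mean(cm[upper.tri(cm)])
    qc_score <- cv_balanced_accuracy(X, factor(ifelse(role_qc, "qc", "study")),
                                     seed = derive_seed(seed, "qc"))
  }
  structure(list(wtr = wtr, qc_correlation = qc_corr,
                 batch_prediction_score = batch_score,
                 qc_prediction_score = qc_score),
            class = "normalization_metrics")
}

#' @export
print.normalization_metrics <- function(x, ...) {
  cat(sprintf("wtr = %s, qc_correlation = %s, batch_prediction = %s, qc_prediction = %s\n",
              fmt_na(x$wtr), fmt_na(x$qc_correlation),
              fmt_na(x$batch_prediction_score), fmt_na(x$qc_prediction_score)))
  invisible(x)
}

fmt_na <- function(x) if (is.na(x)) "NA" else sprintf("%.3f", x)

wtr_score <- function(ab, batch) {
  ub <- unique(batch)
  per_feature <- apply(ab, 1, function(y) {
    tot <- stats::var(y)
    if (!is.finite(tot) || tot == 0) return(NA_real_)
    within <- 0
    for (b in ub) {
      yb <- y[batch == b]
      if (length(yb) >= 2)
        within <- within + sum((yb - mean(yb))^2)
    }
    (within / (length(y) - 1)) / tot
  })
  mean(per_feature, na.rm = TRUE)
}

# stratified k-fold CV balanced accuracy of a small default random forest
cv_balanced_accuracy <- function(X, y, k = 5L, seed = 1L, num_trees = 100L) {
  set.seed(seed)
  y <- droplevels(factor(y))
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  pred <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
  df <- data.frame(X, check.names = FALSE)
  for (fold in seq_len(k)) {
    tr <- folds != fold
    if (length(unique(y[tr])) < 2) next
    fit <- ranger::ranger(x = df[tr, , drop = FALSE], y = y[tr],
                          num.trees = num_trees, seed = derive_seed(seed, fold),
                          num.threads = 1)
    pred[!tr] <- stats::predict(fit, df[!tr, , drop = FALSE],
                                num.threads = 1)$predictions
  }
  recalls <- vapply(levels(y), function(cl) {
    n_cl <- sum(y == cl)
    if (n_cl == 0) return(NA_real_)
    mean(pred[y == cl] == cl)
  }, numeric(1))
  mean(recalls, na.rm = TRUE)
}
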