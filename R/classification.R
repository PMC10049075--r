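#' Oversample classes to a common size
#'
#' Balances a training set by sampling rows with replacement within each
#' class until every class has exactly \code{n_target} rows. When a class
#' has at most \code{n_target} members, each original row is retained at
#' least once (the remainder is drawn with replacement), so no information
#' is discarded.
#'
#' @param X numeric matrix, samples in rows.
#' @param y class labels (factor or character), one per row.
#' @param n_target rows per class after balancing; default 200.
#' @param seed RNG seed.
#' @return A list with the oversampled \code{X} and \code{y}.
#' @export
oversample_balance <- function(X, y, n_target = 200L, seed = 1L) {
  y <- as.factor(y)
  counts <- table(y)
  if (any(counts == 0))
    stop("configuration error: empty class in oversample_balance")
  if (n_target < max(counts))
    stop("configuration error: n_target below the largest class size")
  set.seed(seed)
  idx <- integer(0)
  for (cl in levels(y)) {
    rows <- which(y == cl)
    extra <- sample(rows, n_target - length(rows), replace = TRUE)
    idx <- c(idx, rows, extra)
  }
  list(X = X[idx, , drop = FALSE], y = y[idx])
}

#' Add Gaussian regularization noise
#'
#' Adds i.i.d. Normal(0, sd^2) noise to every entry; applied to training
#' folds only, as a cheap regularizer against the exact duplicates that
#' oversampling creates.
#'
#' @param X numeric matrix.
#' @param sd noise standard deviation; 0 returns \code{X} unchanged.
#' @param seed RNG seed.
#' @return The perturbed matrix.
#' @export
add_noise <- function(X, sd = 0.25, seed = 1L) {
  stopifnot(sd >= 0)
  if (sd == 0) return(X)
  set.seed(seed)
  X + matrix(stats::rnorm(length(X), 0, sd), nrow(X), ncol(X))
}

# vote-fraction class probabilities from a ranger classification forest
vote_probabilities <- function(fit, newdata, class_labels) {
  pr <- stats::predict(fit, data.frame(newdata, check.names = FALSE),
                       predict.all = TRUE, num.threads = 1)$predictions
  if (is.vector(pr)) pr <- matrix(pr, nrow = 1)
  lev <- fit$forest$levels
  probs <- matrix(0, nrow(pr), length(class_labels),
                  dimnames = list(NULL, class_labels))
  for (k in seq_along(lev)) {
    cl <- lev[k]
    if (cl %in% class_labels)
      probs[, cl] <- rowMeans(pr == k)
  }
  probs
}

#' Leave-one-out cross-validated random-forest classification
#'
#' For each sample, a random forest (\code{cfg$n_trees} trees, maximum
#' depth \code{cfg$max_depth}) is trained on all other samples after
#' class-balancing oversampling and additive Gaussian noise — both applied
#' strictly inside the training fold — and the held-out sample's class
#' probabilities (fraction of trees voting per class) are recorded.
#' Aggregate metrics are computed from the held-out probability rows; for
#' binary tasks the ROC over the positive-class probabilities and a
#' bootstrap mean/sd of the AUC are included.
#'
#' @param X numeric matrix, samples in rows (row names = sample ids).
#' @param y class labels, one per row; >= 2 classes.
#' @param cfg a \code{\link{pipeline_config}}.
#' @param seed integer seed for this CV run; defaults to the config's
#'   master seed.
#' @param fold_groups optional vector assigning samples to fold-exclusion
#'   groups: all samples sharing the held-out sample's group are removed
#'   from its training fold (use for technical replicates).
#' @param positive positive class for the ROC; defaults to \code{"UM"}
#'   when present, else the last class label.
#' @return A \code{cv_result}: probabilities, predictions, per-class
#'   precision/recall/F1/support, accuracy, and (binary) \code{roc},
#'   \code{auc_mean}, \code{auc_sd}.
#' @export
loocv_classify <- function(X, y, cfg = pipeline_config(), seed = cfg$master_seed,
                           fold_groups = NULL, positive = NULL) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2)
    stop("configuration error: need >= 2 classes")
  n <- nrow(X)
  if (n < 3) stop("configuration error: need >= 3 samples")
  if (is.null(fold_groups)) fold_groups <- seq_len(n)
  class_labels <- levels(y)
  probs <- matrix(NA_real_, n, length(class_labels),
                  dimnames = list(rownames(X), class_labels))
  for (i in seq_len(n)) {
    tr <- fold_groups != fold_groups[i]
    ytr <- droplevels(y[tr])
    if (nlevels(ytr) < 2)
      stop("configuration error: training fold for sample ", i,
           " has a single class")
    fold_seed <- derive_seed(seed, "fold", i)
    os <- oversample_balance(X[tr, , drop = FALSE], ytr,
                             n_target = cfg$oversample_n,
                             seed = derive_seed(fold_seed, "os"))
    Xn <- add_noise(os$X, sd = cfg$noise_sd,
                    seed = derive_seed(fold_seed, "noise"))
    fit <- ranger::ranger(x = data.frame(Xn, check.names = FALSE), y = os$y,
                          num.trees = cfg$n_trees, max.depth = cfg$max_depth,
                          seed = derive_seed(fold_seed, "rf"),
                          num.threads = 1)
    probs[i, ] <- vote_probabilities(fit, X[i, , drop = FALSE], class_labels)
  }
  finalize_cv_result(probs, y, class_labels, cfg, seed, positive)
}

finalize_cv_result <- function(probs, y, class_labels, cfg, seed, positive) {
  pred_idx <- apply(probs, 1, which.max)   # ties -> first label
  predictions <- factor(class_labels[pred_idx], levels = class_labels)
  per_class <- per_class_metrics(y, predictions, class_labels)
  res <- list(sample_ids = rownames(probs), class_labels = class_labels,
              probabilities = probs, predictions = predictions,
              truth = y, per_class = per_class,
              accuracy = mean(predictions == y),
              config_echo = cfg, seed = seed)
  if (length(class_labels) == 2) {
    if (is.null(positive))
      positive <- if ("UM" %in% class_labels) "UM" else class_labels[2]
    scores <- probs[, positive]
    truth_bin <- y == positive
    res$positive <- positive
    res$roc <- roc_curve(scores, truth_bin)
    ba <- bootstrap_auc(scores, truth_bin, n_boot = cfg$n_boot,
                        seed = derive_seed(seed, "boot"))
    res$auc_mean <- ba[["auc_mean"]]
    res$auc_sd <- ba[["auc_sd"]]
    res$auc_point <- trapezoid_auc(res$roc)
  }
  class(res) <- "cv_result"
  res
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d samples, classes {%s}, accuracy %.3f",
              length(x$sample_ids), paste(x$class_labels, collapse = ", "),
              x$accuracy))
  if (!is.null(x$auc_mean))
    cat(sprintf(", AUC %.3f +/- %.3f", x$auc_mean, x$auc_sd))
  cat("\n")
  invisible(x)
}

per_class_metrics <- function(truth, pred, class_labels) {
  out <- lapply(class_labels, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    c(precision = precision, recall = recall, f1 = f1,
      support = sum(truth == cl))
  })
  names(out) <- class_labels
  out
}

#' ROC curve from scores
#'
#' Builds the ROC by sweeping a threshold over the distinct score values
#' (tied scores move together), from (0,0) to (1,1).
#'
#' @param scores numeric positive-class scores.
#' @param truth logical (or 2-level) vector, TRUE = positive.
#' @return data.frame with columns \code{fpr}, \code{tpr},
#'   \code{threshold}.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  if (!any(truth) || all(truth))
    stop("configuration error: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; t <- truth[o]
  uniq <- !duplicated(s, fromLast = TRUE)   # last index of each tied block
  tp <- cumsum(t)[uniq]; fp <- cumsum(!t)[uniq]
  data.frame(fpr = c(0, fp / sum(!truth)), tpr = c(0, tp / sum(truth)),
             threshold = c(Inf, s[uniq]))
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Bootstrap mean and sd of the ROC AUC
#'
#' Resamples (score, truth) pairs with replacement \code{n_boot} times and
#' computes the AUC of each resample by the trapezoidal ROC rule (with tied
#' scores handled as in the rank / Mann-Whitney formulation); resamples
#' missing a class are redrawn. Returns the mean and the sample (ddof 1)
#' standard deviation.
#'
#' @param scores positive-class scores.
#' @param truth logical vector, TRUE = positive; both classes required.
#' @param n_boot number of resamples; default 25.
#' @param seed RNG seed; the b-th resample is drawn with
#'   \code{sample(n, n, replace = TRUE)} from a stream seeded once, so the
#'   indices are reproducible.
#' @return Named numeric vector \code{c(auc_mean, auc_sd)} with the
#'   per-resample AUCs in attribute \code{"auc_boot"}.
#' @export
bootstrap_auc <- function(scores, truth, n_boot = 25L, seed = 1L) {
  truth <- as.logical(truth)
  if (!any(truth) || all(truth))
    stop("configuration error: both classes must be present")
  n <- length(scores)
  set.seed(seed)
  aucs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(truth[idx]) && !all(truth[idx])) break
    }
    aucs[b] <- trapezoid_auc(roc_curve(scores[idx], truth[idx]))
  }
  out <- c(auc_mean = mean(aucs),
           auc_sd = if (n_boot > 1) stats::sd(aucs) else 0)
  attr(out, "auc_boot") <- aucs
  out
}

#' Repeated 50\%-subsample LOOCV robustness protocol
#'
#' Repeats the full LOOCV procedure \code{cfg$n_repeats} times, each time
#' on a fresh draw of \code{ceil(frac * n_c)} samples per class without
#' replacement, and summarizes the spread of the AUC and per-class F1
#' across repeats — a robustness check on how much the conclusions depend
#' on the particular samples.
#'
#' @inheritParams loocv_classify
#' @return A \code{repeat_summary}: \code{per_repeat} (list of
#'   \code{cv_result}), \code{auc_range}, \code{f1_ranges},
#'   \code{sampled_ids}.
#' @export
repeated_subsample_cv <- function(X, y, cfg = pipeline_config(),
                                  seed = cfg$master_seed, fold_groups = NULL,
                                  positive = NULL) {
  y <- droplevels(as.factor(y))
  frac <- cfg$subsample_frac
  counts <- table(y)
  if (any(ceiling(frac * counts) < 2))
    stop("configuration error: a class would have < 2 samples after subsampling")
  if (is.null(fold_groups)) fold_groups <- seq_len(nrow(X))
  per_repeat <- vector("list", cfg$n_repeats)
  sampled <- vector("list", cfg$n_repeats)
  for (r in seq_len(cfg$n_repeats)) {
    rs <- derive_seed(seed, "repeat", r)
    set.seed(rs)
    idx <- integer(0)
    for (cl in levels(y)) {
      rows <- which(y == cl)
      idx <- c(idx, sample(rows, ceiling(frac * length(rows))))
    }
    idx <- sort(idx)    # original sample order; frac = 1 reduces to plain LOOCV
    per_repeat[[r]] <- loocv_classify(X[idx, , drop = FALSE], y[idx], cfg,
                                      seed = rs,
                                      fold_groups = fold_groups[idx],
                                      positive = positive)
    sampled[[r]] <- rownames(X)[idx]
  }
  aucs <- vapply(per_repeat, function(r)
    if (is.null(r$auc_mean)) NA_real_ else r$auc_mean, numeric(1))
  f1_ranges <- lapply(levels(y), function(cl) {
    f1s <- vapply(per_repeat, function(r) r$per_class[[cl]][["f1"]], numeric(1))
    range(f1s)
  })
  names(f1_ranges) <- levels(y)
  structure(list(per_repeat = per_repeat,
                 auc_range = if (all(is.na(aucs))) c(NA, NA) else range(aucs),
                 f1_ranges = f1_ranges, sampled_ids = sampled,
                 config_echo = cfg, seed = seed),
            class = "repeat_summary")
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat(sprintf("repeat_summary: %d repeats", length(x$per_repeat)))
  if (!all(is.na(x$auc_range)))
    cat(sprintf(", AUC range [%.3f, %.3f]", x$auc_range[1], x$auc_range[2]))
  cat("\n")
  invisible(x)
}

#' Tabulate per-class classification metrics
#'
#' @param result a \code{cv_result}.
#' @return data.frame with one row per class (precision, recall, f1,
#'   support) and the overall accuracy in attribute \code{"accuracy"}.
#' @export
classification_report <- function(result) {
  stopifnot(inherits(result, "cv_result"))
  df <- do.call(rbind, lapply(result$per_class, function(m)
    data.frame(precision = m[["precision"]], recall = m[["recall"]],
               f1 = m[["f1"]], support = m[["support"]])))
  df <- cbind(class = result$class_labels, df)
  rownames(df) <- NULL
  attr(df, "accuracy") <- result$accuracy
  df
}
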