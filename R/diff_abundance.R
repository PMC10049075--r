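#' Per-feature Welch t-tests, cases versus controls
#'
#' Two-sided Welch (unequal-variance) two-sample t-test of every feature's
#' abundance between UM and control study samples. Features where the test
#' is degenerate (both groups essentially constant) get t = 0, p = 1 and a
#' degenerate flag rather than an error.
#'
#' @param ft \code{feature_table} in \code{log1} or \code{z} state.
#' @param meta matching \code{sample_metadata}; both groups need >= 2
#'   study samples.
#' @return data.frame: \code{feature_id}, \code{t_stat}, \code{p_t},
#'   \code{degenerate}.
#' @export
feature_t_tests <- function(ft, meta) {
  if (ft$transform_state == "raw")
    stop("state error: t-tests operate on transformed abundances")
  meta <- meta[match(colnames(ft$abundances), meta$sample_id), ]
  study <- is_study_role(meta$role)
  um <- study & meta$group == "UM"
  ctrl <- study & meta$group == "control"
  if (sum(um) < 2 || sum(ctrl) < 2)
    stop("configuration error: both groups need >= 2 study samples")
  res <- t(apply(ft$abundances, 1, function(y) {
    a <- y[um]; b <- y[ctrl]
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(c(0, 1, 1))
    tt <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(tt)) c(0, 1, 1) else c(tt$statistic, tt$p.value, 0)
  }))
  data.frame(feature_id = ft$feature_ids, t_stat = res[, 1], p_t = res[, 2],
             degenerate = res[, 3] == 1, row.names = NULL)
}

#' Correlation of feature abundance with tumor size
#'
#' Pearson correlation of each feature with the longest tumor diameter
#' (ltd, mm) over UM study samples with a recorded diameter; two-sided p
#' from the t transform of r.
#'
#' @param ft \code{feature_table} in \code{log1} or \code{z} state.
#' @param meta matching \code{sample_metadata}; >= 3 usable UM samples.
#' @return data.frame: \code{feature_id}, \code{r_ltd}, \code{p_r}.
#' @export
ltd_correlation <- function(ft, meta) {
  if (ft$transform_state == "raw")
    stop("state error: correlations operate on transformed abundances")
  meta <- meta[match(colnames(ft$abundances), meta$sample_id), ]
  usable <- is_study_role(meta$role) & meta$group == "UM" & !is.na(meta$ltd)
  m <- sum(usable)
  if (m < 3)
    stop("configuration error: need >= 3 UM samples with ltd")
  ltd <- meta$ltd[usable]
  res <- t(apply(ft$abundances[, usable, drop = FALSE], 1, function(y) {
    if (stats::sd(y) == 0 || stats::sd(ltd) == 0) return(c(0, 1))
    r <- stats::cor(y, ltd)
    if (abs(r) >= 1) return(c(r, 0))
    tv <- r * sqrt((m - 2) / (1 - r^2))
    c(r, 2 * stats::pt(-abs(tv), df = m - 2))
  }))
  data.frame(feature_id = ft$feature_ids, r_ltd = res[, 1], p_r = res[, 2],
             row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param p vector of p-values in (0, 1].
#' @return Adjusted q-values, same order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("validation error: p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' P-value distribution diagnostic
#'
#' Histogram of p-values plus a chi-square uniformity statistic computed
#' over the right-tail bins (p > 0.2). In a well-calibrated screen the
#' right tail is flat (null features) while true signal piles up near 0;
#' departure from right-tail flatness signals mis-calibration
#' (confounding, dependence, a broken test).
#'
#' @param p vector of p-values.
#' @param n_bins number of equal-width bins on [0, 1].
#' @return A list: \code{counts}, \code{breaks}, \code{chisq_stat},
#'   \code{df}, \code{p_uniform} (the uniformity p over right-tail bins),
#'   \code{first_bin_excess} (observed/expected in the leftmost bin).
#' @export
pvalue_histogram_diagnostic <- function(p, n_bins = 20L) {
  if (length(p) == 0) stop("validation error: empty p-vector")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  counts <- as.integer(table(cut(p, breaks, include.lowest = TRUE)))
  tail_bins <- which(breaks[-length(breaks)] >= 0.2)
  obs <- counts[tail_bins]
  if (sum(obs) == 0 || length(obs) < 2) {
    chisq <- Inf; df <- max(1L, length(obs) - 1L); p_unif <- 0
  } else {
    expd <- rep(sum(obs) / length(obs), length(obs))
    chisq <- sum((obs - expd)^2 / expd)
    df <- length(obs) - 1L
    p_unif <- stats::pchisq(chisq, df, lower.tail = FALSE)
  }
  list(counts = counts, breaks = breaks, chisq_stat = chisq, df = df,
       p_uniform = p_unif,
       first_bin_excess = counts[1] / (length(p) / n_bins))
}

#' Differential-abundance screen
#'
#' Runs the per-feature Welch t-test (UM vs control), the tumor-size
#' correlation, BH adjustment of both p-vectors, and flags features where
#' both adjusted values pass \code{alpha} — candidates associated with the
#' disease both in level and in proportion to tumor burden.
#'
#' @param ft \code{feature_table} in \code{log1} or \code{z} state.
#' @param meta matching \code{sample_metadata}.
#' @param alpha FDR level for the joint flag.
#' @return A \code{diff_abundance_result} data.frame: feature_id, mz, rt,
#'   t_stat, p_t, q_t, r_ltd, p_r, q_r, joint_flag.
#' @export
diff_abundance <- function(ft, meta, alpha = 0.05) {
  tt <- feature_t_tests(ft, meta)
  rr <- ltd_correlation(ft, meta)
  out <- data.frame(feature_id = ft$feature_ids, mz = ft$mz, rt = ft$rt,
                    t_stat = tt$t_stat, p_t = tt$p_t,
                    q_t = bh_adjust(tt$p_t),
                    r_ltd = rr$r_ltd, p_r = pmax(rr$p_r, .Machine$double.xmin),
                    row.names = NULL)
  out$q_r <- bh_adjust(out$p_r)
  out$joint_flag <- out$q_t <= alpha & out$q_r <= alpha
  attr(out, "alpha") <- alpha
  class(out) <- c("diff_abundance_result", "data.frame")
  out
}

#' Jointly significant features
#'
#' @param res a \code{diff_abundance_result}.
#' @param alpha FDR level; the flagged sets nest as alpha grows.
#' @return Character vector of feature ids with both adjusted p-values at
#'   or below \code{alpha}.
#' @export
joint_significance <- function(res, alpha = 0.05) {
  res$feature_id[res$q_t <= alpha & res$q_r <= alpha]
}
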