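#' Log-transform a raw feature table
#'
#' Replaces every raw intensity x by log(1 + x) (natural log), so
#' below-detection zeros map to 0 and multiplicative structure becomes
#' additive. Only legal on raw-state tables.
#'
#' @param ft raw-state \code{feature_table}.
#' @return The table in \code{log1} state.
#' @export
log_transform <- function(ft) {
  if (ft$transform_state != "raw")
    stop("state error: log_transform requires a raw-state table (got '",
         ft$transform_state, "')")
  out <- ft
  out$abundances <- log1p(ft$abundances)
  out$transform_state <- "log1"
  out
}

#' Pooled detection threshold
#'
#' Pools all strictly positive entries of the table across features and
#' samples and returns the requested percentile (linear interpolation
#' between order statistics, the type-7 convention). On a log1-state table
#' this is the detection threshold below which abundances are treated as
#' noise by \code{\link{filter_features}}.
#'
#' @param ft \code{feature_table} in \code{log1} state.
#' @param percentile percentile of the non-zero pool, in [0, 100];
#'   default 2.
#' @return Scalar threshold with attributes recording the pool size and
#'   percentile used.
#' @export
pooled_detection_threshold <- function(ft, percentile = 2.0) {
  if (ft$transform_state != "log1")
    stop("state error: threshold is defined on the log1 scale")
  pool <- ft$abundances[ft$abundances > 0]
  if (length(pool) == 0)
    stop("degenerate-input error: no non-zero entries to pool")
  thr <- unname(stats::quantile(pool, probs = percentile / 100, type = 7))
  attr(thr, "n_pooled") <- length(pool)
  attr(thr, "percentile") <- percentile
  thr
}

#' Feature-inclusion filter
#'
#' Keeps a feature when at least \code{min_samples} samples have an
#' abundance strictly above the detection threshold. Row order is
#' preserved. Standard features are exempt from removal (they must survive
#' to anchor normalization) and are flagged instead.
#'
#' @param ft \code{feature_table} in \code{log1} state.
#' @param threshold detection threshold on the log1 scale (from
#'   \code{\link{pooled_detection_threshold}}).
#' @param min_samples minimum number of samples above threshold; default 5.
#' @param standards optional \code{standard_set}; its features are retained
#'   regardless of the count.
#' @return The filtered table; attribute \code{"failed_standards"} lists
#'   exempted standards that would otherwise have been dropped.
#' @export
filter_features <- function(ft, threshold, min_samples = 5L,
                            standards = NULL) {
  if (ft$transform_state != "log1")
    stop("state error: filter operates on the log1 scale")
  counts <- rowSums(ft$abundances > threshold)
  keep <- counts >= min_samples
  failed_std <- character()
  if (!is.null(standards)) {
    std <- ft$feature_ids %in% all_standard_ids(standards)
    failed_std <- ft$feature_ids[std & !keep]
    keep <- keep | std
  }
  out <- subset_features(ft, features = which(keep))
  attr(out, "failed_standards") <- failed_std
  attr(out, "threshold") <- as.numeric(threshold)
  out
}

#' Merge two batches by feature intersection
#'
#' For the merged-dataset path only features detected in both batches are
#' considered: the result keeps the intersection of feature ids (in the
#' first table's order) and concatenates the disjoint sample sets. Per-batch
#' provenance is kept in the \code{"batch_of"} attribute.
#'
#' @param a,b post-filtering \code{feature_table}s of the same ion mode
#'   with disjoint samples.
#' @return The merged \code{feature_table}.
#' @export
merge_batches <- function(a, b) {
  if (a$ion_mode != b$ion_mode)
    stop("schema error: cannot merge ion modes ", a$ion_mode, " and ",
         b$ion_mode)
  if (a$transform_state != b$transform_state)
    stop("state error: batches in different transform states")
  common_samp <- intersect(colnames(a$abundances), colnames(b$abundances))
  if (length(common_samp))
    stop("schema error: batches share samples: ",
         paste(common_samp, collapse = ", "))
  ids <- intersect(a$feature_ids, b$feature_ids)
  ia <- match(ids, a$feature_ids); ib <- match(ids, b$feature_ids)
  ab <- cbind(a$abundances[ia, , drop = FALSE],
              b$abundances[ib, , drop = FALSE])
  out <- feature_table(ids, a$mz[ia], a$rt[ia], a$ion_mode, ab,
                       a$transform_state)
  attr(out, "batch_of") <- c(
    stats::setNames(rep("a", ncol(a$abundances)), colnames(a$abundances)),
    stats::setNames(rep("b", ncol(b$abundances)), colnames(b$abundances)))
  out
}

#' Z-transform features
#'
#' Standardizes every feature row to mean 0 and population (ddof 0) sd 1;
#' constant rows map to all zeros. Applied after normalization, before
#' classification and embedding. Idempotent.
#'
#' @param ft \code{feature_table} in \code{log1} or \code{z} state.
#' @return The table in \code{z} state.
#' @export
z_transform <- function(ft) {
  if (ft$transform_state == "raw")
    stop("state error: z_transform follows the log transform")
  x <- ft$abundances
  m <- rowMeans(x)
  sd_pop <- sqrt(rowMeans((x - m)^2))
  z <- (x - m) / ifelse(sd_pop > 0, sd_pop, 1)
  z[sd_pop == 0, ] <- 0
  out <- ft
  out$abundances <- z
  out$transform_state <- "z"
  out
}
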