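#' Construct a feature-abundance table
#'
#' The central container of the pipeline: an abundance matrix of
#' \code{n_features x n_samples} with per-feature mass-to-charge ratio (m/z,
#' Th), retention time (s) and ionization mode. Raw tables hold non-negative
#' intensities with 0 encoding below-detection; transformed tables hold
#' real values. The transform state moves only forward:
#' \code{raw -> log1 -> z}.
#'
#' @param feature_ids character vector of unique feature identifiers.
#' @param mz numeric vector of mass-to-charge values (Th).
#' @param rt numeric vector of retention times (s).
#' @param ion_mode single string, \code{"positive"} or \code{"negative"};
#'   all features in one table share one mode.
#' @param abundances numeric matrix, features in rows and samples in columns;
#'   column names are sample identifiers.
#' @param transform_state one of \code{"raw"}, \code{"log1"}, \code{"z"}.
#' @return An object of class \code{feature_table}.
#' @export
feature_table <- function(feature_ids, mz, rt, ion_mode, abundances,
                          transform_state = "raw") {
  abundances <- as.matrix(abundances)
  storage.mode(abundances) <- "double"
  ft <- structure(
    list(
      feature_ids = as.character(feature_ids),
      mz = as.numeric(mz),
      rt = as.numeric(rt),
      ion_mode = ion_mode,
      abundances = abundances,
      transform_state = transform_state
    ),
    class = "feature_table"
  )
  rownames(ft$abundances) <- ft$feature_ids
  validate_feature_table(ft)
  ft
}

#' Validate a feature table
#'
#' Checks the structural invariants: matching dimensions, unique feature ids,
#' a single ion mode, no missing cells, non-negative values in raw state and
#' a legal transform state.
#'
#' @param ft a \code{feature_table}.
#' @return \code{ft}, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_feature_table <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  n <- length(ft$feature_ids)
  if (anyDuplicated(ft$feature_ids))
    stop("validation error: duplicated feature_ids: ",
         paste(unique(ft$feature_ids[duplicated(ft$feature_ids)]), collapse = ", "))
  if (length(ft$mz) != n || length(ft$rt) != n)
    stop("validation error: mz/rt length does not match number of features")
  if (!is.character(ft$ion_mode) || length(ft$ion_mode) != 1L ||
      !ft$ion_mode %in% c("positive", "negative"))
    stop("validation error: ion_mode must be 'positive' or 'negative'")
  if (nrow(ft$abundances) != n)
    stop("validation error: abundance matrix has ", nrow(ft$abundances),
         " rows for ", n, " features")
  if (is.null(colnames(ft$abundances)) && ncol(ft$abundances) > 0)
    stop("validation error: abundance matrix lacks sample column names")
  if (anyNA(ft$abundances))
    stop("validation error: missing cells in abundance matrix (encode absence as 0)")
  if (!ft$transform_state %in% c("raw", "log1", "z"))
    stop("validation error: unknown transform_state '", ft$transform_state, "'")
  if (ft$transform_state == "raw" && n > 0 && ncol(ft$abundances) > 0 &&
      any(ft$abundances < 0))
    stop("validation error: negative abundance in raw-state table")
  invisible(ft)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples (%s ion mode, %s state)\n",
              nrow(x$abundances), ncol(x$abundances), x$ion_mode,
              x$transform_state))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$abundances)

sample_ids <- function(ft) colnames(ft$abundances)

#' Subset a feature table by features and/or samples
#'
#' @param ft a \code{feature_table}.
#' @param features character or logical/integer index over features.
#' @param samples character or logical/integer index over samples.
#' @return The subsetted \code{feature_table}.
#' @export
subset_features <- function(ft, features = NULL, samples = NULL) {
  fi <- if (is.null(features)) seq_along(ft$feature_ids) else {
    if (is.character(features)) match(features, ft$feature_ids) else
      seq_along(ft$feature_ids)[features]
  }
  if (anyNA(fi)) stop("schema error: unknown feature ids requested")
  si <- if (is.null(samples)) seq_len(ncol(ft$abundances)) else {
    if (is.character(samples)) match(samples, colnames(ft$abundances)) else
      seq_len(ncol(ft$abundances))[samples]
  }
  if (anyNA(si)) stop("schema error: unknown sample ids requested")
  feature_table(ft$feature_ids[fi], ft$mz[fi], ft$rt[fi], ft$ion_mode,
                ft$abundances[fi, si, drop = FALSE], ft$transform_state)
}

#' Construct per-sample metadata
#'
#' One row per sample. \code{group} is the case/control label (\code{UM} or
#' \code{control}); \code{subclass} carries the secondary-driver subclass
#' (\code{BAP1}, \code{SF3B1}, \code{EIF1AX}) for cases and \code{control}
#' for controls; \code{batch} distinguishes the discovery and replication
#' runs; \code{role} marks study samples, pooled QC injections, blanks and
#' technical replicates (\code{"replicate_of:<sample_id>"}). \code{ltd} is
#' the longest tumor diameter in mm (NA for controls), \code{storage_time}
#' in years.
#'
#' @param df a data.frame with columns \code{sample_id}, \code{group},
#'   \code{subclass}, \code{primary_driver}, \code{batch}, \code{role},
#'   \code{storage_time}, \code{age}, \code{sex}, \code{ltd},
#'   \code{metastasis}. Missing optional columns are filled with NA.
#' @return A validated data.frame of class \code{sample_metadata}.
#' @export
sample_metadata <- function(df) {
  req <- c("sample_id", "group", "subclass", "batch", "role")
  opt <- c("primary_driver", "storage_time", "age", "sex", "ltd", "metastasis")
  missing_req <- setdiff(req, names(df))
  if (length(missing_req))
    stop("schema error: metadata lacks columns: ",
         paste(missing_req, collapse = ", "))
  for (cn in opt) if (!cn %in% names(df)) df[[cn]] <- NA
  df <- df[, c(req, opt)]
  df$sample_id <- as.character(df$sample_id)
  class(df) <- c("sample_metadata", "data.frame")
  validate_sample_metadata(df)
  df
}

#' Validate sample metadata
#'
#' @param meta a \code{sample_metadata} data.frame.
#' @return \code{meta}, invisibly, if valid.
#' @export
validate_sample_metadata <- function(meta) {
  if (anyDuplicated(meta$sample_id))
    stop("validation error: duplicated sample_id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  study <- is_study_role(meta$role)
  bad_group <- study & (!meta$group %in% c("UM", "control"))
  if (any(bad_group))
    stop("validation error: study samples with group outside {UM, control}: ",
         paste(meta$sample_id[bad_group], collapse = ", "))
  # subclass == control <=> group == control (study samples only)
  mism <- study & ((meta$subclass == "control") != (meta$group == "control"))
  if (any(mism, na.rm = TRUE))
    stop("validation error: subclass/control mismatch for: ",
         paste(meta$sample_id[which(mism)], collapse = ", "))
  if (!all(meta$batch %in% c("discovery", "replication")))
    stop("validation error: batch must be 'discovery' or 'replication'")
  ltd <- meta$ltd
  if (any(!is.na(ltd) & ltd <= 0))
    stop("validation error: ltd must be positive when present")
  if (any(!is.na(ltd) & meta$group == "control" & study))
    stop("validation error: controls cannot carry a tumor diameter")
  invisible(meta)
}

is_study_role <- function(role) role == "study"

#' Designate internal and external standard features
#'
#' Spiked isotope-labelled standards anchor the normalization: internal
#' standards supply the principal components regressed out of every feature,
#' external standards are carried for diagnostics.
#'
#' @param internal character vector of feature ids (>= 2 required, PCA needs
#'   at least two rows).
#' @param external character vector of feature ids, disjoint from internal.
#' @return An object of class \code{standard_set}.
#' @export
standard_set <- function(internal, external = character()) {
  internal <- unique(as.character(internal))
  external <- unique(as.character(external))
  if (length(internal) < 2)
    stop("configuration error: need >= 2 internal standards")
  if (length(intersect(internal, external)))
    stop("validation error: internal and external standards overlap: ",
         paste(intersect(internal, external), collapse = ", "))
  structure(list(internal = internal, external = external),
            class = "standard_set")
}

all_standard_ids <- function(standards) {
  c(standards$internal, standards$external)
}

check_standards_in_table <- function(standards, ft) {
  missing <- setdiff(all_standard_ids(standards), ft$feature_ids)
  if (length(missing))
    stop("schema error: standards absent from table: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Pipeline configuration
#'
#' Bundles every tunable constant of the analysis protocol with the
#' published defaults: oversampling to 200 per class, Gaussian regularization
#' noise of sd 0.25, a 150-tree random forest with maximum depth 100, 25
#' bootstrap resamples for the AUC, ten 50\%-subsample repeats, the
#' 2nd-percentile / 5-sample detection filter, the 75\% non-zero eligibility
#' rule and |Z| > 3 outlier exclusion for normalization, and FDR alpha 0.05.
#'
#' @param master_seed integer seed from which all stage seeds are derived.
#' @param oversample_n per-class size after oversampling.
#' @param noise_sd standard deviation of the additive training noise.
#' @param n_trees,max_depth random-forest size.
#' @param n_boot bootstrap resamples for the AUC mean/sd.
#' @param n_repeats,subsample_frac repeated-subsample robustness protocol.
#' @param min_samples_above,pooled_percentile feature-inclusion rule.
#' @param nonzero_frac,z_outlier normalization eligibility and outlier rules.
#' @param fdr_alpha significance level for adjusted p-values.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(master_seed = 1L, oversample_n = 200L,
                            noise_sd = 0.25, n_trees = 150L, max_depth = 100L,
                            n_boot = 25L, n_repeats = 10L,
                            subsample_frac = 0.5, min_samples_above = 5L,
                            pooled_percentile = 2.0, nonzero_frac = 0.75,
                            z_outlier = 3.0, fdr_alpha = 0.05) {
  cfg <- list(master_seed = as.integer(master_seed),
              oversample_n = as.integer(oversample_n),
              noise_sd = noise_sd, n_trees = as.integer(n_trees),
              max_depth = as.integer(max_depth), n_boot = as.integer(n_boot),
              n_repeats = as.integer(n_repeats),
              subsample_frac = subsample_frac,
              min_samples_above = as.integer(min_samples_above),
              pooled_percentile = pooled_percentile,
              nonzero_frac = nonzero_frac, z_outlier = z_outlier,
              fdr_alpha = fdr_alpha)
  stopifnot(cfg$oversample_n >= 1, cfg$noise_sd >= 0, cfg$n_trees >= 1,
            cfg$n_boot >= 1, cfg$subsample_frac > 0, cfg$subsample_frac <= 1,
            cfg$nonzero_frac >= 0, cfg$nonzero_frac <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Derive a stage seed from a master seed
#'
#' One master seed spawns independent, reproducible streams for every fold,
#' repeat and bootstrap via deterministic integer hashing of the tag path.
#' Results always lie in [1, 2^31), safe for \code{set.seed}.
#'
#' @param master_seed integer master seed.
#' @param ... tags (strings or numbers) identifying the consuming stage.
#' @return A single integer seed.
#' @export
derive_seed <- function(master_seed, ...) {
  tags <- paste(c(master_seed, ...), collapse = "/")
  bytes <- utf8ToInt(tags)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h + 1)
}
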