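#' Write a feature table and metadata to delimited text
#'
#' Canonical on-disk format: TSV with features as rows and the columns
#' \code{feature_id, mz, rt, ion_mode} followed by one column per sample,
#' samples sorted by sample id for deterministic output. Numbers are
#' serialized with 12 significant digits so round-trips preserve values to
#' that precision. The metadata is written alongside as a one-row-per-sample
#' TSV.
#'
#' @param ft a \code{feature_table}.
#' @param meta a \code{sample_metadata} data.frame covering exactly the
#'   table's samples.
#' @param path output path for the feature table TSV.
#' @param metadata_path output path for the metadata TSV; defaults to
#'   \code{<path>.meta.tsv}.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(ft, meta, path,
                                metadata_path = paste0(path, ".meta.tsv")) {
  validate_feature_table(ft)
  validate_sample_metadata(meta)
  check_sample_match(ft, meta)
  ord <- order(colnames(ft$abundances))
  ab <- ft$abundances[, ord, drop = FALSE]
  df <- data.frame(feature_id = ft$feature_ids,
                   mz = fmt12(ft$mz), rt = fmt12(ft$rt),
                   ion_mode = rep(ft$ion_mode, length(ft$feature_ids)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(ncol(ab))) df[[colnames(ab)[j]]] <- fmt12(ab[, j])
  con <- file(path, open = "wb")  # binary mode: stable newlines
  on.exit(close(con), add = TRUE)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0)
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  m <- meta[order(meta$sample_id), , drop = FALSE]
  mdf <- as.data.frame(lapply(m, function(col)
    if (is.numeric(col)) fmt12(col) else as.character(col)),
    stringsAsFactors = FALSE)
  mcon <- file(metadata_path, open = "wb")
  on.exit(close(mcon), add = TRUE)
  writeLines(paste(names(mdf), collapse = "\t"), mcon)
  if (nrow(mdf) > 0)
    writeLines(do.call(paste, c(unname(mdf), sep = "\t")), mcon)
  attr(path, "metadata_path") <- metadata_path
  invisible(path)
}

fmt12 <- function(x) {
  out <- formatC(x, digits = 12, format = "g", flag = "")
  out[is.na(x)] <- "NA"
  trimws(out)
}

#' Read a feature table and metadata from delimited text
#'
#' Inverse of \code{\link{write_feature_table}}. Both files are validated
#' and the sample sets cross-checked: every sample column must have a
#' metadata row and vice versa.
#'
#' @param path feature-table TSV path.
#' @param metadata_path metadata TSV path.
#' @param transform_state state of the stored values (\code{"raw"} unless
#'   the file holds transformed abundances).
#' @return A list with elements \code{table} (a \code{feature_table}) and
#'   \code{meta} (a \code{sample_metadata}).
#' @export
read_feature_table <- function(path, metadata_path = paste0(path, ".meta.tsv"),
                               transform_state = "raw") {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  if (!file.exists(metadata_path))
    stop("I/O error: no such file: ", metadata_path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  fixed <- c("feature_id", "mz", "rt", "ion_mode")
  if (!all(fixed %in% names(df)[seq_len(min(4, ncol(df)))]))
    stop("schema error: table must start with columns ",
         paste(fixed, collapse = ", "))
  samp_cols <- setdiff(names(df), fixed)
  ab <- as.matrix(df[, samp_cols, drop = FALSE])
  storage.mode(ab) <- "double"
  colnames(ab) <- samp_cols
  mode <- unique(df$ion_mode)
  if (nrow(df) == 0) mode <- "positive"
  if (length(mode) > 1)
    stop("schema error: mixed ion modes in one file: ",
         paste(mode, collapse = ", "))
  mdf <- utils::read.delim(metadata_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  mdf$sample_id <- as.character(mdf$sample_id)
  meta <- sample_metadata(mdf)
  ft <- feature_table(df$feature_id, as.numeric(df$mz), as.numeric(df$rt),
                      mode, ab, transform_state)
  check_sample_match(ft, meta)
  list(table = ft, meta = meta)
}

check_sample_match <- function(ft, meta) {
  tab_ids <- colnames(ft$abundances)
  extra_tab <- setdiff(tab_ids, meta$sample_id)
  extra_meta <- setdiff(meta$sample_id, tab_ids)
  if (length(extra_tab) || length(extra_meta))
    stop("schema error: sample sets differ",
         if (length(extra_tab)) paste0("; in table only: ",
                                       paste(extra_tab, collapse = ", ")),
         if (length(extra_meta)) paste0("; in metadata only: ",
                                        paste(extra_meta, collapse = ", ")))
  invisible(TRUE)
}

#' Write / read a standards designation as JSON
#'
#' @param standards a \code{standard_set}.
#' @param path JSON file path.
#' @return \code{path} (write) or a \code{standard_set} (read).
#' @export
write_standards <- function(standards, path) {
  jsonlite::write_json(list(internal = standards$internal,
                            external = standards$external),
                       path, pretty = TRUE)
  invisible(path)
}

#' @rdname write_standards
#' @export
read_standards <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  standard_set(x$internal, if (is.null(x$external)) character() else x$external)
}
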