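#' Write a three-file dataset (plus optional ground truth)
#'
#' Writes `features.tsv` (samples x features, sample ids in column 1, missing
#' cells as `NA`), `samples.tsv` (sample metadata) and `feature_meta.tsv`
#' (feature metadata) to `dir`, all UTF-8 and tab-separated with header rows.
#' When `truth` is supplied, `truth.json` is written alongside.
#'
#' @param table A [feature_table()].
#' @param dir Output directory (created if absent).
#' @param truth Optional `synthetic_truth` from [generate_study()].
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(table, dir, truth = NULL) {
  stopifnot(inherits(table, "feature_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  features <- tibble::as_tibble(table$values, rownames = "sample_id")
  readr::write_tsv(features, file.path(dir, "features.tsv"), na = "NA")
  readr::write_tsv(table$sample_meta, file.path(dir, "samples.tsv"))
  readr::write_tsv(table$feature_meta, file.path(dir, "feature_meta.tsv"))
  if (!is.null(truth)) write_truth(truth, file.path(dir, "truth.json"))
  invisible(dir)
}

write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$planted_blocks <- as.list(x$planted_blocks)
  structure(x, class = "synthetic_truth")
}

read_delim_auto <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    na = c("", "NA"))
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    na = c("", "NA"))
  }
}

#' Read and validate a three-file dataset
#'
#' Reads the delimited files written by [write_dataset()] (TSV or CSV; the
#' dialect is chosen by file extension) and assembles a validated
#' [feature_table()]. File row order is preserved. Validation failures name
#' the offending file and identifier.
#'
#' @param features_path Samples-by-features table; sample ids in column 1.
#' @param samples_path Sample metadata (`sample_id`, `subject`, `group`,
#'   `period`, `day`).
#' @param feature_meta_path Feature metadata (`feature_id`, `assay`,
#'   `display_name`).
#' @return A [feature_table()].
#' @export
read_dataset <- function(features_path, samples_path, feature_meta_path) {
  for (p in c(features_path, samples_path, feature_meta_path)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  features <- read_delim_auto(features_path)
  samples <- read_delim_auto(samples_path)
  feature_meta <- read_delim_auto(feature_meta_path)

  if (ncol(features) < 1) {
    abort(sprintf("%s: no columns", features_path))
  }
  sample_ids <- as.character(features[[1]])
  value_cols <- names(features)[-1]

  missing_sample <- setdiff(sample_ids, as.character(samples$sample_id))
  if (length(missing_sample) > 0) {
    abort(sprintf(
      "%s: sample id(s) absent from %s: %s",
      features_path, samples_path,
      paste(utils::head(missing_sample, 5), collapse = ", ")))
  }
  extra_sample <- setdiff(as.character(samples$sample_id), sample_ids)
  if (length(extra_sample) > 0) {
    abort(sprintf(
      "%s: sample id(s) absent from %s: %s",
      samples_path, features_path,
      paste(utils::head(extra_sample, 5), collapse = ", ")))
  }
  missing_feat <- setdiff(value_cols, as.character(feature_meta$feature_id))
  if (length(missing_feat) > 0) {
    abort(sprintf(
      "%s: feature id(s) absent from %s: %s",
      features_path, feature_meta_path,
      paste(utils::head(missing_feat, 5), collapse = ", ")))
  }
  extra_feat <- setdiff(as.character(feature_meta$feature_id), value_cols)
  if (length(extra_feat) > 0) {
    abort(sprintf(
      "%s: feature id(s) absent from %s: %s",
      feature_meta_path, features_path,
      paste(utils::head(extra_feat, 5), collapse = ", ")))
  }

  vals <- as.matrix(features[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- value_cols[!vapply(features[-1], is.numeric, logical(1))]
    abort(sprintf("%s: non-numeric cells in column(s): %s",
                  features_path, paste(utils::head(bad, 5), collapse = ", ")))
  }
  rownames(vals) <- sample_ids

  # preserve file row order: metadata reordered to match the feature matrix
  samples <- samples[match(sample_ids, as.character(samples$sample_id)), ]
  feature_meta <- feature_meta[
    match(value_cols, as.character(feature_meta$feature_id)), ]

  feature_table(vals, samples, feature_meta)
}
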