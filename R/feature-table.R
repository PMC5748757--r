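#' Construct a multi-assay feature table
#'
#' The central data container of the pipeline: a samples-by-features numeric
#' matrix together with per-sample metadata (subject, treatment group,
#' pre/during/post period, collection day) and per-feature metadata (assay of
#' origin, display name). Missing measurements are `NA` in `values` and stay
#' `NA`; they are never silently zero-filled.
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#'   Row/column names, when present, must agree with the metadata ids.
#' @param sample_meta Data frame with columns `sample_id`, `subject`, `group`,
#'   `period` (one of `"pre"`, `"during"`, `"post"`) and `day` (integer), one
#'   row per row of `values`.
#' @param feature_meta Data frame with columns `feature_id`, `assay` (one of
#'   `"fecal_metabolite"`, `"urinary_metabolite"`, `"taxon"`, `"element"`) and
#'   `display_name`, one row per column of `values`.
#'
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, sample_meta, feature_meta) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  sample_meta <- tibble::as_tibble(sample_meta)
  feature_meta <- tibble::as_tibble(feature_meta)

  need_s <- c("sample_id", "subject", "group", "period", "day")
  missing_s <- setdiff(need_s, names(sample_meta))
  if (length(missing_s) > 0) {
    abort(sprintf("sample_meta is missing column(s): %s",
                  paste(missing_s, collapse = ", ")))
  }
  need_f <- c("feature_id", "assay", "display_name")
  missing_f <- setdiff(need_f, names(feature_meta))
  if (length(missing_f) > 0) {
    abort(sprintf("feature_meta is missing column(s): %s",
                  paste(missing_f, collapse = ", ")))
  }
  sample_meta$sample_id <- as.character(sample_meta$sample_id)
  sample_meta$subject <- as.character(sample_meta$subject)
  sample_meta$group <- as.character(sample_meta$group)
  sample_meta$period <- as.character(sample_meta$period)
  sample_meta$day <- as.integer(sample_meta$day)
  feature_meta$feature_id <- as.character(feature_meta$feature_id)
  feature_meta$assay <- as.character(feature_meta$assay)
  feature_meta$display_name <- as.character(feature_meta$display_name)

  if (nrow(values) != nrow(sample_meta)) {
    abort(sprintf("values has %d rows but sample_meta has %d",
                  nrow(values), nrow(sample_meta)))
  }
  if (ncol(values) != nrow(feature_meta)) {
    abort(sprintf("values has %d columns but feature_meta has %d rows",
                  ncol(values), nrow(feature_meta)))
  }
  dup <- sample_meta$sample_id[duplicated(sample_meta$sample_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate sample id(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  dup <- feature_meta$feature_id[duplicated(feature_meta$feature_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate feature id(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  bad_assay <- setdiff(unique(feature_meta$assay), names(ASSAYS))
  if (length(bad_assay) > 0) {
    abort(sprintf("unknown assay label(s): %s (allowed: %s)",
                  paste(bad_assay, collapse = ", "),
                  paste(names(ASSAYS), collapse = ", ")))
  }
  bad_period <- setdiff(unique(sample_meta$period), PERIODS)
  if (length(bad_period) > 0) {
    abort(sprintf("unknown period label(s): %s (allowed: %s)",
                  paste(bad_period, collapse = ", "),
                  paste(PERIODS, collapse = ", ")))
  }
  if (anyNA(sample_meta)) {
    abort("sample_meta must be complete (no NA entries)")
  }
  if (any(is.infinite(values))) {
    abort("values must be finite or NA; found infinite entries")
  }
  if (!is.null(rownames(values)) &&
      !identical(unname(rownames(values)), sample_meta$sample_id)) {
    abort("rownames(values) disagree with sample_meta$sample_id")
  }
  if (!is.null(colnames(values)) &&
      !identical(unname(colnames(values)), feature_meta$feature_id)) {
    abort("colnames(values) disagree with feature_meta$feature_id")
  }
  rownames(values) <- sample_meta$sample_id
  colnames(values) <- feature_meta$feature_id

  structure(
    list(values = values, sample_meta = sample_meta,
         feature_meta = feature_meta),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$feature_meta$assay)
  cat("  assays:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  cat("  groups:", paste(unique(x$sample_meta$group), collapse = ", "), "\n")
  n_na <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.1f%%)\n",
              n_na, 100 * n_na / length(x$values)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Long-format view of a feature table
#'
#' @param x A [feature_table()].
#' @param ... Unused.
#' @return A tibble with one row per (sample, feature) cell, carrying the
#'   sample and feature metadata alongside `value`.
#' @export
tidy.feature_table <- function(x, ...) {
  long <- tibble::as_tibble(x$values, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "feature_id",
                        values_to = "value")
  long |>
    dplyr::left_join(x$sample_meta, by = "sample_id") |>
    dplyr::left_join(x$feature_meta, by = "feature_id")
}

#' @export
glance.feature_table <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$values),
    n_features = ncol(x$values),
    n_subjects = dplyr::n_distinct(x$sample_meta$subject),
    n_groups = dplyr::n_distinct(x$sample_meta$group),
    n_missing = sum(is.na(x$values))
  )
}

# Select samples by metadata predicate; returns a feature_table.
filter_samples <- function(table, keep) {
  stopifnot(inherits(table, "feature_table"), is.logical(keep),
            length(keep) == nrow(table$values))
  feature_table(table$values[keep, , drop = FALSE],
                table$sample_meta[keep, , drop = FALSE],
                table$feature_meta)
}

# Select features by id; returns a feature_table.
select_features <- function(table, feature_ids) {
  stopifnot(inherits(table, "feature_table"))
  idx <- match(feature_ids, table$feature_meta$feature_id)
  if (anyNA(idx)) {
    abort(sprintf("unknown feature id(s): %s",
                  paste(feature_ids[is.na(idx)], collapse = ", ")))
  }
  feature_table(table$values[, idx, drop = FALSE],
                table$sample_meta,
                table$feature_meta[idx, , drop = FALSE])
}
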