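#' Convert one assay's values to percentages
#'
#' Rescales each sample's sub-vector of the selected assay so it sums to 100,
#' leaving all other assays untouched. Already-relative rows are unchanged
#' (the operation is idempotent). Missing cells are ignored in the row sum
#' and stay missing.
#'
#' @param table A [feature_table()].
#' @param assay Assay to rescale (default `"taxon"`).
#' @return A [feature_table()] with the assay on the percent scale.
#' @export
to_percentages <- function(table, assay = "taxon") {
  stopifnot(inherits(table, "feature_table"))
  ids <- table$feature_meta$feature_id[table$feature_meta$assay == assay]
  if (length(ids) == 0) return(table)
  sub <- table$values[, ids, drop = FALSE]
  if (any(sub < 0, na.rm = TRUE)) {
    abort(sprintf("assay '%s' has negative values; cannot rescale", assay))
  }
  sums <- rowSums(sub, na.rm = TRUE)
  observed <- rowSums(!is.na(sub)) > 0
  zero <- observed & sums <= 0
  if (any(zero)) {
    abort(sprintf("all-zero %s row for sample(s): %s", assay,
                  paste(utils::head(rownames(sub)[zero], 5), collapse = ", ")))
  }
  vals <- table$values
  vals[observed, ids] <- 100 * sub[observed, , drop = FALSE] / sums[observed]
  feature_table(vals, table$sample_meta, table$feature_meta)
}

#' Combine assay tables into one dataset
#'
#' Outer-joins feature tables on (subject, collection day): the combined
#' table has one row per subject-day present in any input, features
#' concatenated in input order, and measurements absent for a subject-day
#' marked missing. Rows are ordered by subject then day. Conflicting group
#' (or period) labels for the same subject-day are an error.
#'
#' @param tables A list of [feature_table()] objects with a shared
#'   subject/day vocabulary.
#' @return A combined [feature_table()] keyed by subject and day; sample ids
#'   are `subject_dNN`.
#' @export
align_assays <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1,
            all(vapply(tables, inherits, logical(1), "feature_table")))

  all_feat <- dplyr::bind_rows(lapply(tables, function(t) t$feature_meta))
  dup <- all_feat$feature_id[duplicated(all_feat$feature_id)]
  if (length(dup) > 0) {
    abort(sprintf("feature id(s) present in more than one table: %s",
                  paste(unique(utils::head(dup, 5)), collapse = ", ")))
  }

  keys <- dplyr::bind_rows(lapply(tables, function(t) {
    t$sample_meta[, c("subject", "day", "group", "period")]
  })) |> dplyr::distinct()
  conflict <- keys |>
    dplyr::count(.data$subject, .data$day) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflict) > 0) {
    abort(sprintf(
      "conflicting group/period metadata for subject-day(s): %s",
      paste(utils::head(sprintf("%s day %d", conflict$subject, conflict$day), 5),
            collapse = ", ")))
  }
  keys <- keys[order(keys$subject, keys$day), ]
  keys$sample_id <- sprintf("%s_d%02d", keys$subject, keys$day)

  vals <- matrix(NA_real_, nrow(keys), nrow(all_feat),
                 dimnames = list(keys$sample_id, all_feat$feature_id))
  for (t in tables) {
    row_idx <- match(paste(t$sample_meta$subject, t$sample_meta$day),
                     paste(keys$subject, keys$day))
    vals[row_idx, t$feature_meta$feature_id] <- t$values
  }

  feature_table(vals, keys[, c("sample_id", "subject", "group", "period",
                               "day")], all_feat)
}

#' Unit-variance (auto)scale a feature table
#'
#' Centers every feature and divides by its sample standard deviation
#' (denominator n - 1, computed over non-missing entries), so each retained
#' feature has mean 0 and SD 1. Features with fewer than two observations or
#' zero variance cannot be scaled; they are dropped with a warning and
#' recorded in `scaling_params`.
#'
#' @param table A [feature_table()].
#' @return An object of class `scaled_table`: the scaled `values` matrix with
#'   sample/feature metadata, and `scaling_params`, a tibble of per-feature
#'   `(mean, sd, dropped)` allowing exact inversion of the transform.
#' @export
unit_variance <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  n_obs <- colSums(!is.na(table$values))
  mu <- colMeans(table$values, na.rm = TRUE)
  sdev <- apply(table$values, 2, sd, na.rm = TRUE)

  dropped <- n_obs < 2 | is.na(sdev) | sdev == 0
  if (any(dropped)) {
    warn(sprintf(
      "dropping %d feature(s) with < 2 observations or zero variance: %s",
      sum(dropped),
      paste(utils::head(colnames(table$values)[dropped], 5), collapse = ", ")))
  }

  params <- tibble::tibble(
    feature_id = colnames(table$values),
    mean = unname(mu),
    sd = unname(sdev),
    n_obs = unname(n_obs),
    dropped = unname(dropped)
  )
  keep <- !dropped
  vals <- sweep(table$values[, keep, drop = FALSE], 2, mu[keep], "-")
  vals <- sweep(vals, 2, sdev[keep], "/")

  structure(
    list(values = vals,
         sample_meta = table$sample_meta,
         feature_meta = table$feature_meta[keep, , drop = FALSE],
         scaling_params = params),
    class = "scaled_table"
  )
}

#' @export
print.scaled_table <- function(x, ...) {
  cat(sprintf("<scaled_table> %d samples x %d features (unit variance)\n",
              nrow(x$values), ncol(x$values)))
  n_drop <- sum(x$scaling_params$dropped)
  if (n_drop > 0) cat(sprintf("  %d feature(s) dropped in scaling\n", n_drop))
  invisible(x)
}

#' @export
dim.scaled_table <- function(x) dim(x$values)

# Undo unit_variance for the retained features.
unscale <- function(scaled) {
  stopifnot(inherits(scaled, "scaled_table"))
  params <- scaled$scaling_params
  keep <- params[!params$dropped, ]
  idx <- match(colnames(scaled$values), keep$feature_id)
  vals <- sweep(scaled$values, 2, keep$sd[idx], "*")
  sweep(vals, 2, keep$mean[idx], "+")
}

# Complete (no-missing) feature submatrix of a scaled table, or zero-imputed
# values, depending on policy. Imputing the post-scaling mean is imputing 0.
scaled_values_complete <- function(scaled,
                                   policy = c("complete_features", "impute_mean")) {
  policy <- match.arg(policy)
  vals <- scaled$values
  if (!anyNA(vals)) return(vals)
  if (policy == "complete_features") {
    vals[, colSums(is.na(vals)) == 0, drop = FALSE]
  } else {
    vals[is.na(vals)] <- 0
    vals
  }
}
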