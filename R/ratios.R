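#' Abundance ratio of two taxon sets
#'
#' Per-sample ratio of summed relative abundances, e.g. the
#' Firmicutes/Bacteroidetes ratio commonly reported as a gut lifestyle
#' indicator. Taxa are matched by a regular expression against their
#' display names.
#'
#' @param table A [feature_table()] whose taxon assay is on the percent
#'   scale (see [to_percentages()]).
#' @param numerator,denominator Regular expressions matched against taxon
#'   display names (defaults: `"^Firmicutes"`, `"^Bacteroidetes"`).
#' @return A tibble with one row per sample: `sample_id`, the summed
#'   abundances and `ratio`; the mean and SD over samples are attached as
#'   attributes `mean` and `sd`.
#' @export
abundance_ratio <- function(table, numerator = "^Firmicutes",
                            denominator = "^Bacteroidetes") {
  stopifnot(inherits(table, "feature_table"))
  fm <- table$feature_meta
  tax <- fm[fm$assay == "taxon", ]
  num_ids <- tax$feature_id[grepl(numerator, tax$display_name)]
  den_ids <- tax$feature_id[grepl(denominator, tax$display_name)]
  if (length(num_ids) == 0 || length(den_ids) == 0) {
    abort("numerator or denominator pattern matched no taxa")
  }
  out <- tibble::tibble(
    sample_id = table$sample_meta$sample_id,
    numerator = rowSums(table$values[, num_ids, drop = FALSE], na.rm = TRUE),
    denominator = rowSums(table$values[, den_ids, drop = FALSE],
                          na.rm = TRUE)
  )
  out$ratio <- ifelse(out$denominator > 0, out$numerator / out$denominator,
                      NA_real_)
  attr(out, "mean") <- mean(out$ratio, na.rm = TRUE)
  attr(out, "sd") <- sd(out$ratio, na.rm = TRUE)
  out
}
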