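#' Configure a synthetic feeding study
#'
#' Describes the simulated study design: a three-arm feeding experiment
#' (cellulose control and two test foods), a handful of subjects per arm,
#' longitudinal sampling across pre/during/post feeding periods, and four
#' assays whose feature counts default to a total of 490 variables. A weak
#' treatment effect of standardised size `effect_size` is planted into
#' `n_planted` features, organised in `n_blocks` correlated blocks, for the
#' affected group during the `during` and `post` periods.
#'
#' @param n_groups Number of treatment groups (default 3).
#' @param n_subjects_per_group Subjects per group (default 4).
#' @param n_days Collection days per subject, split evenly into pre/during/post
#'   periods (default 18, giving 216 fecal collections with the defaults).
#' @param n_fecal_metabolites,n_urinary_metabolites,n_taxa,n_elements Feature
#'   counts per assay (defaults 160, 180, 130, 20; total 490).
#' @param n_planted Number of treatment-affected features (default 10).
#' @param n_blocks Number of correlated blocks the planted features are split
#'   into (default 2).
#' @param effect_size Standardised mean shift delta, in units of a feature's
#'   within-condition SD (subject-to-subject plus day-to-day), applied on the
#'   log scale (default 1).
#' @param block_corr Latent-factor loading in \[0, 1); pairwise correlation
#'   within a planted block is `block_corr^2` (default 0.9).
#' @param subject_sd SD of the per-subject random offset each feature carries,
#'   relative to a day-level residual SD of 1 (default 1).
#' @param missing_urine_fraction Fraction of subject-days whose urinary
#'   measurements (urinary metabolites and elements) are missing
#'   (default 33/216, leaving 183 of 216 urine collections).
#' @param plant_assay Assay receiving the planted effect:
#'   `"fecal_metabolite"` (default) or `"taxon"`.
#' @param affected_group 1-based index of the group receiving the shift
#'   (default `n_groups`, the *M. struthiopteris*-like arm).
#' @param seed Integer seed; one RNG stream per generated dataset.
#'
#' @return An object of class `study_config` (a named list).
#' @seealso [generate_study()], [null_study()]
#' @export
study_config <- function(n_groups = 3,
                         n_subjects_per_group = 4,
                         n_days = 18,
                         n_fecal_metabolites = 160,
                         n_urinary_metabolites = 180,
                         n_taxa = 130,
                         n_elements = 20,
                         n_planted = 10,
                         n_blocks = 2,
                         effect_size = 1,
                         block_corr = 0.9,
                         subject_sd = 1,
                         missing_urine_fraction = 33 / 216,
                         plant_assay = c("fecal_metabolite", "taxon"),
                         affected_group = n_groups,
                         seed = 1L) {
  plant_assay <- match.arg(plant_assay)
  config <- list(
    n_groups = n_groups,
    n_subjects_per_group = n_subjects_per_group,
    n_days = n_days,
    n_fecal_metabolites = n_fecal_metabolites,
    n_urinary_metabolites = n_urinary_metabolites,
    n_taxa = n_taxa,
    n_elements = n_elements,
    n_planted = n_planted,
    n_blocks = n_blocks,
    effect_size = effect_size,
    block_corr = block_corr,
    subject_sd = subject_sd,
    missing_urine_fraction = missing_urine_fraction,
    plant_assay = plant_assay,
    affected_group = affected_group,
    seed = seed
  )
  validate_study_config(config)
}

config_error <- function(field, msg) {
  abort(sprintf("invalid study_config field `%s`: %s", field, msg),
        class = "gutnet_config_error")
}

validate_study_config <- function(config) {
  counts <- c("n_groups", "n_subjects_per_group", "n_days",
              "n_fecal_metabolites", "n_urinary_metabolites", "n_taxa",
              "n_elements", "n_blocks")
  for (f in counts) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != floor(v)) {
      config_error(f, "must be a single integer >= 1")
    }
    config[[f]] <- as.integer(v)
  }
  v <- config$n_planted
  if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != floor(v)) {
    config_error("n_planted", "must be a single integer >= 0")
  }
  config$n_planted <- as.integer(v)
  plant_pool <- switch(config$plant_assay,
                       fecal_metabolite = config$n_fecal_metabolites,
                       taxon = config$n_taxa)
  if (config$n_planted > plant_pool) {
    config_error("n_planted",
                 sprintf("exceeds the %d features of the %s assay",
                         plant_pool, config$plant_assay))
  }
  if (config$n_planted > 0 && config$n_blocks > config$n_planted) {
    config_error("n_blocks", "cannot exceed n_planted")
  }
  if (!is.numeric(config$effect_size) || length(config$effect_size) != 1 ||
      is.na(config$effect_size) || config$effect_size < 0) {
    config_error("effect_size", "must be a single number >= 0")
  }
  if (!is.numeric(config$block_corr) || length(config$block_corr) != 1 ||
      is.na(config$block_corr) || config$block_corr < 0 ||
      config$block_corr >= 1) {
    config_error("block_corr", "must lie in [0, 1)")
  }
  if (!is.numeric(config$subject_sd) || length(config$subject_sd) != 1 ||
      is.na(config$subject_sd) || config$subject_sd < 0) {
    config_error("subject_sd", "must be a single number >= 0")
  }
  v <- config$missing_urine_fraction
  if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v >= 1) {
    config_error("missing_urine_fraction", "must lie in [0, 1)")
  }
  if (!is.numeric(config$affected_group) || length(config$affected_group) != 1 ||
      is.na(config$affected_group) || config$affected_group < 1 ||
      config$affected_group > config$n_groups ||
      config$affected_group != floor(config$affected_group)) {
    config_error("affected_group",
                 sprintf("must be an integer in 1..%d", config$n_groups))
  }
  config$affected_group <- as.integer(config$affected_group)
  if (!is.numeric(config$seed) || length(config$seed) != 1 ||
      is.na(config$seed) || config$seed != floor(config$seed) ||
      abs(config$seed) >= 2^31) {
    config_error("seed", "must be a single 32-bit integer")
  }
  config$seed <- as.integer(config$seed)
  structure(config, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  p_total <- x$n_fecal_metabolites + x$n_urinary_metabolites + x$n_taxa +
    x$n_elements
  cat(sprintf(
    "<study_config> %d groups x %d subjects x %d days; %d features\n",
    x$n_groups, x$n_subjects_per_group, x$n_days, p_total))
  cat(sprintf(
    "  planted: %d in %d block(s) of %s, delta = %g, block_corr = %g\n",
    x$n_planted, x$n_blocks, x$plant_assay, x$effect_size, x$block_corr))
  cat(sprintf("  subject_sd = %g, missing urine fraction = %.3f, seed = %d\n",
              x$subject_sd, x$missing_urine_fraction, x$seed))
  invisible(x)
}
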