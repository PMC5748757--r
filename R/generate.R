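#' Generate a synthetic longitudinal feeding study
#'
#' Simulates the feature table of a three-arm mouse feeding study with known
#' ground truth. Metabolite-like assays (fecal/urinary metabolites, urinary
#' elements) are log-normal: each feature has a baseline log-mean, a
#' per-subject random offset (SD `subject_sd`) and unit day-level residual
#' noise. Planted features additionally load on a block-level latent factor
#' (loading `block_corr`, giving within-block correlation `block_corr^2`) and
#' receive an additive shift of `effect_size` within-condition SDs on the log
#' scale for the affected group during the `during` and `post` periods.
#' Microbial taxa are logistic-normal compositions scaled to percentages
#' (each sample's taxa sum to 100). Urinary measurements are removed for a
#' fixed fraction of subject-days, chosen uniformly at random.
#'
#' The whole dataset is drawn from a single RNG stream seeded with
#' `config$seed`, so equal configurations yield bit-identical output.
#'
#' @param config A [study_config()].
#' @return A list with elements `table` (a [feature_table()]) and `truth`
#'   (a `synthetic_truth` object recording the planted feature ids, their
#'   block structure, the effect size and the affected group/periods).
#' @export
generate_study <- function(config) {
  config <- validate_study_config(unclass(config))
  withr::with_seed(config$seed, generate_study_impl(config))
}

#' Generate a null study (no treatment effect)
#'
#' [generate_study()] with `effect_size` forced to 0; every feature is
#' exchangeable across groups by construction. Used to measure the
#' family-wise false-report rate of the full pipeline.
#'
#' @inheritParams generate_study
#' @return As [generate_study()]; `truth$forced_null` is `TRUE`.
#' @export
null_study <- function(config) {
  config <- validate_study_config(unclass(config))
  config$effect_size <- 0
  out <- generate_study(config)
  out$truth$forced_null <- TRUE
  out
}

group_labels <- function(n_groups) {
  base <- c("cellulose", "P_aquilinum", "M_struthiopteris")
  if (n_groups <= 3) base[seq_len(n_groups)]
  else c(base, sprintf("group%d", seq(4, n_groups)))
}

period_of_day <- function(day, n_days) {
  b1 <- round(n_days / 3)
  b2 <- round(2 * n_days / 3)
  ifelse(day <= b1, "pre", ifelse(day <= b2, "during", "post"))
}

generate_study_impl <- function(config) {
  n_sub_total <- config$n_groups * config$n_subjects_per_group
  n <- n_sub_total * config$n_days

  subject_idx <- rep(seq_len(n_sub_total), each = config$n_days)
  group_idx <- rep(rep(seq_len(config$n_groups),
                       each = config$n_subjects_per_group),
                   each = config$n_days)
  day <- rep(seq_len(config$n_days), times = n_sub_total)
  period <- period_of_day(day, config$n_days)

  groups <- group_labels(config$n_groups)
  subjects <- sprintf("m%02d", seq_len(n_sub_total))
  sample_meta <- tibble::tibble(
    sample_id = sprintf("%s_d%02d", subjects[subject_idx], day),
    subject = subjects[subject_idx],
    group = groups[group_idx],
    period = period,
    day = as.integer(day)
  )

  affected <- groups[config$affected_group]
  shift_on <- as.numeric(sample_meta$group == affected &
                           sample_meta$period %in% c("during", "post"))
  # delta is expressed in within-condition SDs: subject-level variance
  # subject_sd^2 plus day-level variance 1
  wc_sd <- sqrt(1 + config$subject_sd^2)
  shift <- config$effect_size * wc_sd * shift_on

  feature_meta <- make_feature_meta(config)
  p_total <- nrow(feature_meta)

  # planted block assignment (contiguous blocks within the planted assay)
  planted_ids <- character(0)
  blocks <- list()
  if (config$n_planted > 0) {
    pool <- feature_meta$feature_id[feature_meta$assay == config$plant_assay]
    planted_ids <- pool[seq_len(config$n_planted)]
    block_of <- sort(rep_len(seq_len(config$n_blocks), config$n_planted))
    blocks <- split(planted_ids, sprintf("block%d", block_of))
  }

  values <- matrix(NA_real_, n, p_total,
                   dimnames = list(sample_meta$sample_id,
                                   feature_meta$feature_id))

  draw_noise <- function(p) {
    # per-subject random offset plus unit day-level residual, per feature
    u <- matrix(rnorm(n_sub_total * p, 0, config$subject_sd), ncol = p)
    u[subject_idx, , drop = FALSE] + matrix(rnorm(n * p), n, p)
  }

  plant <- function(noise, cols) {
    # overwrite planted columns with latent-factor structure and add the
    # treatment shift; marginal variance and subject-offset SD are unchanged
    lam <- config$block_corr
    for (b in seq_along(blocks)) {
      shared <- rnorm(n_sub_total, 0, config$subject_sd)[subject_idx] + rnorm(n)
      for (id in blocks[[b]]) {
        unique_part <- rnorm(n_sub_total, 0, config$subject_sd)[subject_idx] +
          rnorm(n)
        noise[, match(id, cols)] <- lam * shared +
          sqrt(1 - lam^2) * unique_part
      }
    }
    noise[, match(planted_ids, cols)] <-
      noise[, match(planted_ids, cols), drop = FALSE] + shift
    noise
  }

  met_assays <- c("fecal_metabolite", "urinary_metabolite", "element")
  for (assay in met_assays) {
    ids <- feature_meta$feature_id[feature_meta$assay == assay]
    p <- length(ids)
    if (p == 0) next
    mu <- runif(p, 0, 3)
    noise <- draw_noise(p)
    if (assay == config$plant_assay && config$n_planted > 0) {
      noise <- plant(noise, ids)
    }
    values[, ids] <- exp(sweep(noise, 2, mu, "+"))
  }

  ids <- feature_meta$feature_id[feature_meta$assay == "taxon"]
  if (length(ids) > 0) {
    p <- length(ids)
    mu <- rnorm(p, 0, 1.5)
    eta <- draw_noise(p)
    if (config$plant_assay == "taxon" && config$n_planted > 0) {
      eta <- plant(eta, ids)
    }
    eta <- sweep(eta, 2, mu, "+")
    comp <- exp(eta)
    values[, ids] <- 100 * comp / rowSums(comp)
  }

  # remove urinary measurements (urinary metabolites + elements) for a fixed
  # number of subject-days, chosen uniformly at random
  urine_ids <- feature_meta$feature_id[
    feature_meta$assay %in% c("urinary_metabolite", "element")]
  n_drop <- round(config$missing_urine_fraction * n)
  if (n_drop > 0 && length(urine_ids) > 0) {
    drop_rows <- sample(n, n_drop)
    values[drop_rows, urine_ids] <- NA_real_
  }

  truth <- structure(
    list(
      planted_feature_ids = planted_ids,
      planted_blocks = blocks,
      effect_size = config$effect_size,
      affected_group = affected,
      affected_periods = c("during", "post"),
      plant_assay = config$plant_assay,
      forced_null = config$effect_size == 0,
      seed = config$seed
    ),
    class = "synthetic_truth"
  )

  list(table = feature_table(values, sample_meta, feature_meta),
       truth = truth)
}

make_feature_meta <- function(config) {
  elements <- c("Ca", "Mg", "Zn", "K", "Na", "P", "Fe", "Cu", "Mn", "Se",
                "Sr", "B", "Ba", "Al", "Ni", "Co", "Cr", "Mo", "Li", "V")
  n_el <- config$n_elements
  el_names <- if (n_el <= length(elements)) elements[seq_len(n_el)]
              else c(elements, sprintf("El%02d", seq(length(elements) + 1, n_el)))

  n_tx <- config$n_taxa
  phyla <- rep("Proteobacteria", n_tx)
  phyla[seq_len(round(0.45 * n_tx))] <- "Firmicutes"
  if (round(0.45 * n_tx) < n_tx) {
    bact <- seq(round(0.45 * n_tx) + 1, min(n_tx, round(0.8 * n_tx)))
    phyla[bact] <- "Bacteroidetes"
  }

  dplyr::bind_rows(
    tibble::tibble(
      feature_id = sprintf("fm:peak%03d", seq_len(config$n_fecal_metabolites)),
      assay = "fecal_metabolite",
      display_name = sprintf("f.peak_%03d", seq_len(config$n_fecal_metabolites))
    ),
    tibble::tibble(
      feature_id = sprintf("um:peak%03d", seq_len(config$n_urinary_metabolites)),
      assay = "urinary_metabolite",
      display_name = sprintf("u.peak_%03d",
                             seq_len(config$n_urinary_metabolites))
    ),
    tibble::tibble(
      feature_id = sprintf("el:%s", el_names),
      assay = "element",
      display_name = el_names
    ),
    tibble::tibble(
      feature_id = sprintf("tx:taxon%03d", seq_len(n_tx)),
      assay = "taxon",
      display_name = sprintf("%s|taxon_%03d", phyla, seq_len(n_tx))
    )
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d planted feature(s) in %d block(s)\n",
              length(x$planted_feature_ids), length(x$planted_blocks)))
  cat(sprintf("  effect_size = %g (%s), affected: %s in %s\n",
              x$effect_size, x$plant_assay, x$affected_group,
              paste(x$affected_periods, collapse = "/")))
  invisible(x)
}
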