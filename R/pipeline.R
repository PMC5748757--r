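#' Configure an end-to-end pipeline run
#'
#' Collects every tunable of the pipeline in one object. Either a synthetic
#' `study` configuration or the three dataset paths must be given. All
#' defaulted values are echoed into the run manifest, so a run is fully
#' reconstructible from its manifest.
#'
#' @param study A [study_config()] to simulate from, or `NULL` when reading
#'   from files.
#' @param features_path,samples_path,feature_meta_path Dataset files, used
#'   when `study` is `NULL`.
#' @param forest A [forest_params()]; its seed is derived from `seed` unless
#'   supplied explicitly.
#' @param label_mode Classification target, see [group_period_labels()].
#' @param rf_missing Missing-value policy for the classifier matrix:
#'   `"impute_mean"` (default; post-scaling means are 0) or
#'   `"complete_features"`.
#' @param n_components Components kept in the PCA (default 2).
#' @param mds_k Dimensions of the proximity MDS embedding (default 2).
#' @param threshold Absolute-Spearman edge cutoff (default 0.6).
#' @param min_pairs Minimum complete observation pairs per edge (default 10).
#' @param top_k Number of important factors extracted (default 30).
#' @param test_periods Periods entering the group tests (default
#'   during/post).
#' @param holm_family Holm family scope, `"all"` or `"per_factor"`.
#' @param alpha Family-wise significance level (default 0.05).
#' @param cross_validation Run the k-fold over-training guard (default
#'   `TRUE`).
#' @param n_folds Folds for the guard (default 5).
#' @param write_plots Also write PCA/MDS/importance figures (default
#'   `TRUE`; requires an output directory).
#' @param out_dir Output directory, or `NULL` to keep results in memory.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(study = NULL,
                            features_path = NULL, samples_path = NULL,
                            feature_meta_path = NULL,
                            forest = NULL,
                            label_mode = c("pooled_pre", "treated_only"),
                            rf_missing = c("impute_mean", "complete_features"),
                            n_components = 2,
                            mds_k = 2,
                            threshold = 0.6,
                            min_pairs = 10,
                            top_k = 30,
                            test_periods = c("during", "post"),
                            holm_family = c("all", "per_factor"),
                            alpha = 0.05,
                            cross_validation = TRUE,
                            n_folds = 5,
                            write_plots = TRUE,
                            out_dir = NULL,
                            seed = 1L) {
  label_mode <- match.arg(label_mode)
  rf_missing <- match.arg(rf_missing)
  holm_family <- match.arg(holm_family)
  if (is.null(study) &&
      (is.null(features_path) || is.null(samples_path) ||
         is.null(feature_meta_path))) {
    abort("either `study` or all three dataset paths must be given")
  }
  if (!is.null(study)) study <- validate_study_config(unclass(study))
  structure(
    list(study = study, features_path = features_path,
         samples_path = samples_path, feature_meta_path = feature_meta_path,
         forest = forest, label_mode = label_mode, rf_missing = rf_missing,
         n_components = n_components, mds_k = mds_k, threshold = threshold,
         min_pairs = min_pairs, top_k = top_k, test_periods = test_periods,
         holm_family = holm_family, alpha = alpha,
         cross_validation = cross_validation, n_folds = n_folds,
         write_plots = write_plots, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# deterministic fan-out of the global seed to per-stage seeds
stage_seed <- function(seed, stage) {
  offsets <- c(data = 0L, forest = 1000003L, cv = 2000003L)
  (seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full detection pipeline
#'
#' Executes simulate/load, percentage conversion, unit-variance scaling,
#' PCA, random-forest importance with the optional cross-validation guard,
#' proximity MDS, the Spearman correlation network, community detection,
#' overlay of the top-k factors, Holm-corrected group tests and the module
#' report, in that order. Any stage error aborts the run, naming the stage;
#' when an output directory is set the manifest (including the error
#' record) is written regardless.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; defaults to `config$out_dir`. `NULL`
#'   keeps all results in memory.
#' @return A `gutnet_run` with every stage result and `manifest`; the
#'   manifest's `status` is `"modules_detected"` when any module factor has
#'   Holm-adjusted p below `alpha`, otherwise `"no_modules_detected"`.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(
    package_version = as.character(packageVersion("gutnet")),
    seed = config$seed,
    config = serialize_config(config),
    stages = list(),
    status = "error"
  )
  run <- list()
  stage <- function(name, expr) {
    result <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      if (!is.null(out_dir)) write_manifest(manifest, out_dir)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(status = "completed")
    result
  }

  # --- data -----------------------------------------------------------
  truth <- NULL
  table <- stage("data", {
    if (!is.null(config$study)) {
      study <- config$study
      study$seed <- stage_seed(config$seed, "data") + study$seed - 1L
      sim <- generate_study(study)
      truth <- sim$truth
      sim$table
    } else {
      read_dataset(config$features_path, config$samples_path,
                   config$feature_meta_path)
    }
  })
  table <- stage("percentages", to_percentages(table, "taxon"))
  manifest$stages$data$n_samples <- nrow(table$values)
  manifest$stages$data$n_features <- ncol(table$values)

  # --- preprocess -----------------------------------------------------
  scaled <- stage("scaling", suppressWarnings(unit_variance(table)))
  manifest$stages$scaling$n_features_retained <- ncol(scaled$values)

  # --- ordination baseline -------------------------------------------
  pca_fit <- stage("pca", pca(scaled, n_components = config$n_components))
  pca_sil <- group_silhouette(pca_fit$scores, scaled$sample_meta$group)
  manifest$stages$pca$group_silhouette <- pca_sil

  # --- forest ---------------------------------------------------------
  fparams <- config$forest %||% forest_params()
  if (is.null(config$forest)) {
    fparams$seed <- stage_seed(config$seed, "forest")
  }
  labels <- group_period_labels(scaled$sample_meta, config$label_mode)
  keep_rows <- !is.na(labels)
  rf_vals <- scaled_values_complete(scaled, config$rf_missing)
  model <- stage("forest", fit_forest(rf_vals[keep_rows, , drop = FALSE],
                                      labels[keep_rows], fparams))
  importance <- importance_mda(model)
  top <- top_factors(importance, k = min(config$top_k, nrow(importance)))
  manifest$stages$forest$oob_error <- model$oob_error
  cv <- NULL
  if (isTRUE(config$cross_validation)) {
    cv_params <- fparams
    cv_params$seed <- stage_seed(config$seed, "cv")
    cv <- stage("cross_validation",
                cross_validate(rf_vals[keep_rows, , drop = FALSE],
                               labels[keep_rows], cv_params,
                               n_folds = config$n_folds,
                               oob_error = model$oob_error))
    manifest$stages$cross_validation$cv_error <- cv$cv_error
  }
  mds <- stage("mds", classical_mds(proximity_distance(rf_proximity(model)),
                                    k = config$mds_k))

  # --- correlation network -------------------------------------------
  network <- stage("network", {
    corr <- spearman_matrix(table)
    build_network(corr, threshold = config$threshold,
                  min_pairs = config$min_pairs,
                  feature_meta = table$feature_meta)
  })
  partition <- stage("communities", detect_communities(network))
  manifest$stages$network$n_edges <- nrow(network$edges)
  manifest$stages$communities$n_communities <-
    dplyr::n_distinct(partition$membership$community)
  manifest$stages$communities$modularity <- partition$modularity

  # --- integration ----------------------------------------------------
  overlay <- stage("overlay", overlay_modules(partition, top))
  tests <- stage("tests", suppressWarnings(
    test_module_factors(table, overlay, periods = config$test_periods,
                        family = config$holm_family)))
  report <- stage("report",
                  module_report(overlay, tests, network, importance, table))

  detected <- nrow(tests) > 0 && any(tests$p_holm < config$alpha)
  manifest$status <- if (detected) "modules_detected" else "no_modules_detected"
  manifest$n_significant_factors <- report$n_significant

  run <- structure(
    list(table = table, truth = truth, scaled = scaled, pca = pca_fit,
         pca_silhouette = pca_sil, model = model, importance = importance,
         top_factors = top, cv = cv, mds = mds, network = network,
         partition = partition, overlay = overlay, tests = tests,
         report = report, manifest = manifest),
    class = "gutnet_run"
  )
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir, config)
  run
}

serialize_config <- function(config) {
  out <- unclass(config)
  out$study <- if (!is.null(config$study)) unclass(config$study)
  out$forest <- if (!is.null(config$forest)) unclass(config$forest)
  out$out_dir <- NULL
  out
}

write_manifest <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

write_run_artifacts <- function(run, dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(run$manifest, dir)
  readr::write_tsv(tidy(run$pca), file.path(dir, "pca_scores.tsv"))
  readr::write_tsv(tidy(run$mds), file.path(dir, "mds_coordinates.tsv"))
  imp <- tidy(run$importance)
  imp$selected_top_k <- imp$feature_id %in% run$top_factors
  imp$assay <- run$table$feature_meta$assay[
    match(imp$feature_id, run$table$feature_meta$feature_id)]
  readr::write_tsv(imp[order(imp$rank), ], file.path(dir, "importance.tsv"))
  readr::write_tsv(tidy(run$partition), file.path(dir, "partition.tsv"))
  write_network(run$network, run$partition, run$top_factors,
                file.path(dir, "network.graphml"), format = "graphml")
  write_module_report(run$report, dir)
  if (isTRUE(config$write_plots)) {
    save_plot <- function(p, name) {
      grDevices::png(file.path(dir, name), width = 1200, height = 900,
                     res = 150)
      print(p)
      grDevices::dev.off()
    }
    save_plot(autoplot(run$pca), "pca.png")
    save_plot(autoplot_mds_run(run), "mds.png")
    save_plot(plot_importance(run$importance, k = length(run$top_factors)),
              "importance.png")
  }
  invisible(dir)
}

#' @export
print.gutnet_run <- function(x, ...) {
  cat("<gutnet_run>\n")
  cat(sprintf("  status: %s (%d significant factor(s))\n",
              x$manifest$status, x$report$n_significant))
  cat(sprintf("  OOB error %.3f | PCA silhouette %.3f | %d edges, Q = %.3f\n",
              x$model$oob_error, x$pca_silhouette, nrow(x$network$edges),
              x$partition$modularity))
  cat(sprintf("  %d selected module(s)\n",
              length(x$overlay$selected_communities)))
  invisible(x)
}

#' @export
glance.gutnet_run <- function(x, ...) {
  tibble::tibble(
    status = x$manifest$status,
    oob_error = x$model$oob_error,
    cv_error = if (!is.null(x$cv)) x$cv$cv_error else NA_real_,
    pca_silhouette = x$pca_silhouette,
    n_edges = nrow(x$network$edges),
    modularity = x$partition$modularity,
    n_modules = length(x$overlay$selected_communities),
    n_significant = x$report$n_significant
  )
}
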