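#' Random-forest hyperparameters
#'
#' Defaults mirror the standard classification settings of the randomForest
#' implementation: 500 trees, `mtry = floor(sqrt(p))`, nodes grown to purity.
#'
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split; `NULL` (default) means
#'   `floor(sqrt(p))` at fit time.
#' @param min_leaf Minimum terminal-node size (default 1).
#' @param seed Integer seed controlling bootstrap, split and permutation
#'   randomness.
#' @return A `forest_params` list.
#' @export
forest_params <- function(n_trees = 500, mtry = NULL, min_leaf = 1,
                          seed = 1L) {
  stopifnot(is.numeric(n_trees), length(n_trees) == 1, n_trees >= 1)
  if (!is.null(mtry)) stopifnot(is.numeric(mtry), length(mtry) == 1, mtry >= 1)
  stopifnot(is.numeric(min_leaf), length(min_leaf) == 1, min_leaf >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_leaf = as.integer(min_leaf), seed = as.integer(seed)),
            class = "forest_params")
}

#' Classification target for the feeding-study design
#'
#' The default grouping used for the random forest: pre-period samples of
#' all arms pooled into one `"pre"` class, and during/post samples labelled
#' by their treatment group — the grouping under which a food-specific
#' response is a class of its own.
#'
#' @param sample_meta Sample metadata tibble (columns `group`, `period`).
#' @param mode `"pooled_pre"` (default, 1 + n_groups classes),
#'   `"treated_only"` (during/post samples only, labelled by group; pre
#'   samples get `NA` and should be dropped by the caller) or
#'   `"one_vs_rest"` (binary: `target` group's during/post samples against
#'   everything else).
#' @param target Group label for `mode = "one_vs_rest"`.
#' @return A factor of class labels, one per sample.
#' @export
group_period_labels <- function(sample_meta,
                                mode = c("pooled_pre", "treated_only",
                                         "one_vs_rest"),
                                target = NULL) {
  mode <- match.arg(mode)
  if (mode == "one_vs_rest") {
    if (is.null(target) || !target %in% sample_meta$group) {
      abort("one_vs_rest mode needs `target`, one of the group labels")
    }
    treated <- sample_meta$group == target & sample_meta$period != "pre"
    return(factor(ifelse(treated, target, "rest"),
                  levels = c(target, "rest")))
  }
  lab <- ifelse(sample_meta$period == "pre",
                if (mode == "pooled_pre") "pre" else NA_character_,
                sample_meta$group)
  factor(lab)
}

#' Fit a random-forest classifier of treatment groups
#'
#' An ensemble of classification trees, each grown on a bootstrap sample
#' with Gini splits over `mtry` randomly drawn features; out-of-bag votes,
#' permutation importance and the sample proximity matrix are recorded
#' during the fit. Deterministic given `params$seed`.
#'
#' @param scaled A `scaled_table` from [unit_variance()] or a numeric matrix
#'   without missing values.
#' @param labels Class label per sample (factor or character); see
#'   [group_period_labels()].
#' @param params A [forest_params()].
#' @return An object of class `gutnet_forest`.
#' @export
fit_forest <- function(scaled, labels, params = forest_params()) {
  vals <- if (inherits(scaled, "scaled_table")) scaled$values
          else as.matrix(scaled)
  if (anyNA(vals)) {
    abort(paste("missing values present; impute or restrict to complete",
                "features before fitting (see scaled_values_complete policy",
                "in run_pipeline)"))
  }
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2) abort("need >= 2 classes to fit a classifier")
  if (any(table(labels) < 2)) {
    abort("every class needs >= 2 samples")
  }
  if (length(labels) != nrow(vals)) {
    abort("labels length must equal the number of samples")
  }
  mtry <- params$mtry %||% max(1, floor(sqrt(ncol(vals))))
  if (mtry > ncol(vals)) abort("mtry cannot exceed the number of features")

  fit <- withr::with_seed(params$seed, randomForest::randomForest(
    x = vals, y = labels,
    ntree = params$n_trees, mtry = mtry, nodesize = params$min_leaf,
    importance = TRUE, proximity = TRUE, keep.forest = TRUE
  ))
  oob_error <- mean(fit$predicted != labels)

  structure(
    list(fit = fit, params = params, labels = labels,
         feature_ids = colnames(vals), oob_error = oob_error,
         n_samples = nrow(vals)),
    class = "gutnet_forest"
  )
}

#' @export
print.gutnet_forest <- function(x, ...) {
  cat(sprintf("<gutnet_forest> %d trees, %d samples, %d features\n",
              x$params$n_trees, x$n_samples, length(x$feature_ids)))
  cat(sprintf("  OOB error: %.3f over %d classes\n", x$oob_error,
              nlevels(x$labels)))
  invisible(x)
}

#' @export
glance.gutnet_forest <- function(x, ...) {
  tibble::tibble(
    n_trees = x$params$n_trees,
    mtry = x$fit$mtry,
    n_samples = x$n_samples,
    n_features = length(x$feature_ids),
    n_classes = nlevels(x$labels),
    oob_error = x$oob_error
  )
}

#' Mean-decrease-in-accuracy importance
#'
#' Per feature: for each tree, the classification accuracy on that tree's
#' out-of-bag samples minus the accuracy after permuting the feature's
#' values among them, averaged over trees (the raw, unscaled permutation
#' importance). Ranks are dense, 1-based, by non-increasing importance.
#'
#' @param model A `gutnet_forest` from [fit_forest()].
#' @return An `importance_result`: a tibble with `feature_id`, `mda`, `rank`,
#'   carrying `oob_error` as an attribute.
#' @export
importance_mda <- function(model) {
  stopifnot(inherits(model, "gutnet_forest"))
  imp <- randomForest::importance(model$fit, type = 1, scale = FALSE)
  out <- tibble::tibble(
    feature_id = rownames(imp),
    mda = unname(imp[, "MeanDecreaseAccuracy"])
  )
  out$rank <- dplyr::dense_rank(dplyr::desc(out$mda))
  attr(out, "oob_error") <- model$oob_error
  class(out) <- c("importance_result", class(out))
  out
}

#' @export
tidy.importance_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Extract the top-k important factors
#'
#' The `k` features of highest mean decrease in accuracy; exact ties are
#' broken lexicographically by feature id, so the selection is
#' deterministic.
#'
#' @param importance An `importance_result` from [importance_mda()].
#' @param k Number of factors (default 30).
#' @return Character vector of `k` feature ids, in selection order.
#' @export
top_factors <- function(importance, k = 30) {
  if (k > nrow(importance)) {
    abort(sprintf("k = %d exceeds the %d available features",
                  k, nrow(importance)))
  }
  ord <- order(-importance$mda, importance$feature_id)
  importance$feature_id[ord][seq_len(k)]
}

#' Random-forest proximity matrix
#'
#' `proximity[i, j]` is the fraction of trees in which samples i and j land
#' in the same terminal node; the diagonal is 1.
#'
#' @param model A `gutnet_forest` from [fit_forest()].
#' @return A symmetric n x n matrix in \[0, 1\].
#' @export
rf_proximity <- function(model) {
  stopifnot(inherits(model, "gutnet_forest"))
  model$fit$proximity
}

#' Cross-validated error of the forest classifier
#'
#' Stratified k-fold cross-validation: forests are refit per fold with
#' fold-specific seeds derived from `params$seed`. If the cross-validated
#' error exceeds the out-of-bag error by more than 0.1, a warning flags
#' possible over-training. `n_folds` equal to the sample count requests
#' leave-one-out.
#'
#' @inheritParams fit_forest
#' @param n_folds Number of folds (default 5).
#' @param oob_error Optional OOB error of the full fit, for the
#'   over-training guard.
#' @return A list with `cv_error`, `fold_errors` and `n_folds`.
#' @export
cross_validate <- function(scaled, labels, params = forest_params(),
                           n_folds = 5, oob_error = NULL) {
  vals <- if (inherits(scaled, "scaled_table")) scaled$values
          else as.matrix(scaled)
  labels <- droplevels(factor(labels))
  n <- nrow(vals)

  if (n_folds == n) {
    fold_of <- seq_len(n)   # leave-one-out
  } else {
    too_small <- table(labels) < n_folds
    if (any(too_small)) {
      abort(sprintf(
        "class(es) %s have fewer than %d members; use fewer folds",
        paste(names(too_small)[too_small], collapse = ", "), n_folds))
    }
    fold_of <- integer(n)
    withr::with_seed(params$seed, {
      for (cl in levels(labels)) {
        idx <- which(labels == cl)
        fold_of[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
    })
  }

  fold_errors <- vapply(seq_len(max(fold_of)), function(f) {
    test <- fold_of == f
    fold_params <- params
    fold_params$seed <- params$seed + f
    fit <- withr::with_seed(fold_params$seed, randomForest::randomForest(
      x = vals[!test, , drop = FALSE], y = labels[!test],
      ntree = params$n_trees,
      mtry = params$mtry %||% max(1, floor(sqrt(ncol(vals)))),
      nodesize = params$min_leaf
    ))
    pred <- predict(fit, vals[test, , drop = FALSE])
    mean(pred != labels[test])
  }, numeric(1))

  cv_error <- mean(fold_errors)
  if (!is.null(oob_error) && cv_error > oob_error + 0.1) {
    warn(sprintf(
      "possible over-training: cv_error %.3f exceeds oob_error %.3f by > 0.1",
      cv_error, oob_error))
  }
  list(cv_error = cv_error, fold_errors = fold_errors,
       n_folds = max(fold_of))
}
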