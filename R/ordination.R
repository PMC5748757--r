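#' Principal component analysis of a scaled table
#'
#' PCA by singular value decomposition of the (re)centered data matrix. On
#' unit-variance data this is correlation-matrix PCA. The analysed submatrix
#' must be complete: by default only features observed on every sample enter
#' (`missing = "complete_features"`); `missing = "impute_mean"` fills missing
#' cells with the feature mean instead. Within each component, the loading of
#' largest magnitude is made positive, fixing the sign convention.
#'
#' @param scaled A `scaled_table` from [unit_variance()] (a bare numeric
#'   matrix is also accepted).
#' @param n_components Number of components to keep (default
#'   `min(n - 1, p)`).
#' @param missing Missing-value policy, see above. With `"error"`, missing
#'   values raise an error naming the policies.
#' @return An object of class `gutnet_pca` with `scores`
#'   (samples x components), `loadings` (features x components, orthonormal
#'   columns) and `explained_variance_ratio` (squared singular values over
#'   their total across all components).
#' @export
pca <- function(scaled, n_components = NULL,
                missing = c("complete_features", "impute_mean", "error")) {
  missing <- match.arg(missing)
  sample_meta <- NULL
  if (inherits(scaled, "scaled_table")) {
    sample_meta <- scaled$sample_meta
    vals <- scaled$values
  } else {
    vals <- as.matrix(scaled)
  }
  if (anyNA(vals)) {
    if (missing == "error") {
      abort(paste("missing values present; choose a completion policy:",
                  "missing = 'complete_features' or 'impute_mean'"))
    }
    vals <- if (missing == "complete_features") {
      vals[, colSums(is.na(vals)) == 0, drop = FALSE]
    } else {
      apply(vals, 2, function(v) {
        v[is.na(v)] <- mean(v, na.rm = TRUE)
        v
      })
    }
  }
  if (ncol(vals) < 1) abort("no complete features available for PCA")

  centered <- sweep(vals, 2, colMeans(vals), "-")
  sv <- svd(centered)
  ev <- sv$d^2
  ratio <- ev / sum(ev)
  k <- min(n_components %||% length(sv$d), length(sv$d))

  loadings <- sv$v[, seq_len(k), drop = FALSE]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  # sign convention: largest-magnitude loading positive per component
  flip <- vapply(seq_len(k), function(j) {
    sign(loadings[which.max(abs(loadings[, j])), j])
  }, numeric(1))
  loadings <- sweep(loadings, 2, flip, "*")
  scores <- sweep(scores, 2, flip, "*")
  dimnames(scores) <- list(rownames(vals), sprintf("PC%d", seq_len(k)))
  dimnames(loadings) <- list(colnames(vals), sprintf("PC%d", seq_len(k)))

  structure(
    list(scores = scores, loadings = loadings,
         explained_variance_ratio = ratio[seq_len(k)],
         sample_meta = sample_meta),
    class = "gutnet_pca"
  )
}

#' @export
print.gutnet_pca <- function(x, ...) {
  cat(sprintf("<gutnet_pca> %d samples, %d component(s)\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained_variance_ratio, 5)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.gutnet_pca <- function(x, ...) {
  out <- tibble::as_tibble(x$scores, rownames = "sample_id")
  if (!is.null(x$sample_meta)) {
    out <- dplyr::left_join(out, x$sample_meta, by = "sample_id")
  }
  out
}

#' @export
glance.gutnet_pca <- function(x, ...) {
  tibble::tibble(
    n_components = ncol(x$scores),
    pc1_var = x$explained_variance_ratio[1],
    pc2_var = if (ncol(x$scores) >= 2) x$explained_variance_ratio[2]
              else NA_real_
  )
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix and embeds the top `k`
#' eigenvectors scaled by the square roots of their eigenvalues. Negative
#' eigenvalues (non-Euclidean input) are truncated at zero, with a message.
#'
#' @param distance Symmetric non-negative matrix with zero diagonal.
#' @param k Embedding dimension (default 2).
#' @return An object of class `gutnet_mds` with `coordinates`
#'   (n x k) and `eigenvalues` (all n, non-increasing).
#' @export
classical_mds <- function(distance, k = 2) {
  distance <- as.matrix(distance)
  n <- nrow(distance)
  if (ncol(distance) != n) abort("distance matrix must be square")
  if (max(abs(distance - t(distance))) > 1e-9) {
    abort("distance matrix must be symmetric (tolerance 1e-9)")
  }
  if (any(abs(diag(distance)) > 1e-9)) {
    abort("distance matrix must have zero diagonal")
  }
  if (k < 1 || k > n) abort("k must lie in 1..n")

  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (distance^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  if (any(ev < -1e-9 * max(abs(ev), 1))) {
    inform(sprintf(
      "classical_mds: %d negative eigenvalue(s) truncated at zero",
      sum(ev < -1e-9 * max(abs(ev), 1))))
  }
  pos <- pmax(ev, 0)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(k)]), k)
  dimnames(coords) <- list(rownames(distance),
                           sprintf("MDS%d", seq_len(k)))
  structure(list(coordinates = coords, eigenvalues = ev),
            class = "gutnet_mds")
}

#' @export
print.gutnet_mds <- function(x, ...) {
  cat(sprintf("<gutnet_mds> %d points in %d dimension(s)\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  invisible(x)
}

#' @export
tidy.gutnet_mds <- function(x, ...) {
  tibble::as_tibble(x$coordinates, rownames = "sample_id")
}

#' Distance matrix from random-forest proximities
#'
#' The standard transform `d = sqrt(1 - proximity)`, turning the proximity
#' similarity into a dissimilarity suitable for [classical_mds()].
#'
#' @param proximity Symmetric proximity matrix in \[0, 1\].
#' @return A distance matrix of the same shape.
#' @export
proximity_distance <- function(proximity) {
  d <- sqrt(pmax(1 - proximity, 0))
  diag(d) <- 0
  d
}

#' Mean silhouette width of group labels in an ordination
#'
#' The average silhouette of `groups` over the first two columns of a score
#' or coordinate matrix; values near 0 mean the groups do not separate in
#' that plane.
#'
#' @param coords Numeric matrix of scores/coordinates (first two columns
#'   used).
#' @param groups Group label per row.
#' @return Mean silhouette width (scalar).
#' @export
group_silhouette <- function(coords, groups) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  groups <- as.character(groups)
  stopifnot(nrow(coords) == length(groups))
  D <- as.matrix(stats::dist(coords))
  sil <- vapply(seq_along(groups), function(i) {
    own <- setdiff(which(groups == groups[i]), i)
    if (length(own) == 0) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(groups), groups[i]),
                    function(g) mean(D[i, groups == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}
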