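#' Spearman rank correlation matrix of a feature table
#'
#' Pairwise-complete Spearman correlation: for each feature pair, the
#' Pearson correlation of midranks computed over samples where both are
#' observed (the tie-robust form). The number of complete pairs per entry is
#' recorded so downstream edges can require a minimum overlap.
#'
#' @param table A [feature_table()], `scaled_table` or numeric matrix.
#' @return A `correlation_matrix`: list of `rho` (p x p, diagonal 1) and
#'   `n_pairs` (complete observation pairs per entry).
#' @export
spearman_matrix <- function(table) {
  vals <- if (inherits(table, c("feature_table", "scaled_table"))) {
    table$values
  } else {
    as.matrix(table)
  }
  if (nrow(vals) < 3) abort("need >= 3 samples for rank correlation")
  n_pairs <- crossprod(!is.na(vals))
  rho <- spearman_pairwise(vals)
  diag(rho) <- 1
  structure(list(rho = rho, n_pairs = n_pairs),
            class = "correlation_matrix")
}

# Pairwise-complete Spearman. When columns share few distinct missingness
# patterns (structured missingness: whole assays absent on the same
# subject-days), the pairwise-complete row set depends only on the two
# patterns, so the matrix is assembled blockwise from Pearson correlations
# of midranks -- exactly the generic pairwise computation, much faster.
spearman_pairwise <- function(vals) {
  obs <- !is.na(vals)
  pattern_key <- apply(obs, 2, function(o) paste(which(!o), collapse = ","))
  patterns <- unique(pattern_key)
  if (length(patterns) > 16) {
    return(suppressWarnings(
      cor(vals, method = "spearman", use = "pairwise.complete.obs")))
  }
  p <- ncol(vals)
  rho <- matrix(NA_real_, p, p, dimnames = list(colnames(vals),
                                                colnames(vals)))
  cols_of <- lapply(patterns, function(k) which(pattern_key == k))
  rows_of <- lapply(cols_of, function(cols) obs[, cols[1]])
  for (i in seq_along(patterns)) {
    for (j in i:length(patterns)) {
      rows <- rows_of[[i]] & rows_of[[j]]
      ci <- cols_of[[i]]
      cj <- cols_of[[j]]
      if (sum(rows) < 3) next
      ri <- apply(vals[rows, ci, drop = FALSE], 2, rank)
      rj <- if (i == j) ri else apply(vals[rows, cj, drop = FALSE], 2, rank)
      block <- suppressWarnings(cor(ri, rj))
      rho[ci, cj] <- block
      rho[cj, ci] <- t(block)
    }
  }
  rho
}

#' Build a thresholded correlation network
#'
#' Nodes are all features; an edge joins features i and j when
#' `|rho(i, j)| >= threshold` and at least `min_pairs` complete observation
#' pairs support the estimate. Edge weight is `|rho|`; the correlation sign
#' is kept as an attribute. Isolated nodes are retained (they become
#' singleton communities downstream).
#'
#' @param corr A `correlation_matrix` from [spearman_matrix()].
#' @param threshold Absolute-correlation cutoff in \[0, 1\] (default 0.6);
#'   0 keeps the complete weighted graph.
#' @param min_pairs Minimum complete pairs per edge (default 10).
#' @param feature_meta Optional feature metadata tibble supplying the
#'   `assay` node attribute.
#' @return A `correlation_network`: `nodes` (tibble `feature_id`, `assay`),
#'   `edges` (tibble `from`, `to`, `weight`, `rho`, `sign`), plus the
#'   `threshold` and `min_pairs` used.
#' @export
build_network <- function(corr, threshold = 0.6, min_pairs = 10,
                          feature_meta = NULL) {
  stopifnot(inherits(corr, "correlation_matrix"))
  if (threshold < 0 || threshold > 1) abort("threshold must lie in [0, 1]")
  rho <- corr$rho
  ids <- colnames(rho)

  keep <- !is.na(rho) & abs(rho) >= threshold & corr$n_pairs >= min_pairs
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  rho_e <- rho[idx]
  edges <- tibble::tibble(
    from = ids[idx[, 1]],
    to = ids[idx[, 2]],
    weight = abs(rho_e),
    rho = rho_e,
    sign = ifelse(rho_e >= 0, 1L, -1L)
  )
  # canonical orientation and deterministic order
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]

  nodes <- tibble::tibble(feature_id = ids)
  nodes$assay <- if (!is.null(feature_meta)) {
    feature_meta$assay[match(ids, feature_meta$feature_id)]
  } else {
    NA_character_
  }

  structure(
    list(nodes = nodes, edges = edges, threshold = threshold,
         min_pairs = min_pairs),
    class = "correlation_network"
  )
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf(
    "<correlation_network> %d nodes, %d edges (|rho| >= %g, >= %d pairs)\n",
    nrow(x$nodes), nrow(x$edges), x$threshold, x$min_pairs))
  invisible(x)
}

#' Weighted Newman modularity of a partition
#'
#' `Q = sum_c [ w_c / W - (s_c / 2W)^2 ]` with `w_c` the intra-community
#' edge weight, `s_c` the summed strength of the community's nodes and `W`
#' the total edge weight.
#'
#' @param network A `correlation_network`.
#' @param membership Named community assignment (one label per network
#'   node), or the `membership` tibble of a `network_partition`.
#' @return Modularity Q (0 for an empty network).
#' @export
modularity_q <- function(network, membership) {
  stopifnot(inherits(network, "correlation_network"))
  if (is.data.frame(membership)) {
    membership <- stats::setNames(membership$community, membership$feature_id)
  }
  ids <- network$nodes$feature_id
  uncovered <- setdiff(ids, names(membership))
  if (length(uncovered) > 0) {
    abort(sprintf("membership does not cover node(s): %s",
                  paste(utils::head(uncovered, 5), collapse = ", ")))
  }
  edges <- network$edges
  if (nrow(edges) == 0) return(0)
  W <- sum(edges$weight)
  strength <- rep(0, length(ids))
  names(strength) <- ids
  for (side in c("from", "to")) {
    s <- tapply(edges$weight, edges[[side]], sum)
    strength[names(s)] <- strength[names(s)] + s
  }
  comm <- membership[ids]
  intra <- tapply(edges$weight[comm[edges$from] == comm[edges$to]],
                  comm[edges$from][comm[edges$from] == comm[edges$to]], sum)
  s_c <- tapply(strength, comm, sum)
  w_c <- rep(0, length(s_c))
  names(w_c) <- names(s_c)
  if (length(intra) > 0) w_c[names(intra)] <- intra
  sum(w_c / W - (s_c / (2 * W))^2)
}

#' Detect network communities by greedy modularity maximisation
#'
#' Clauset-Newman-Moore agglomeration on edge weights: starting from
#' singleton communities, repeatedly merge the pair of connected communities
#' with the largest modularity gain while any gain is positive. Exact ties
#' are broken by the lexicographically smallest community-label pair, so the
#' result is deterministic. Isolated nodes remain singleton communities.
#'
#' @param network A `correlation_network`.
#' @param method `"greedy"` (default, the deterministic agglomeration
#'   described above) or `"multilevel"` (Louvain-style multilevel
#'   optimisation, run with a fixed internal seed).
#' @return A `network_partition`: `membership` (tibble `feature_id`,
#'   `community` with dense labels from 0, numbered by each community's
#'   lexicographically smallest member) and `modularity`.
#' @export
detect_communities <- function(network, method = c("greedy", "multilevel")) {
  stopifnot(inherits(network, "correlation_network"))
  method <- match.arg(method)
  if (method == "multilevel") return(detect_communities_multilevel(network))
  ids <- sort(network$nodes$feature_id)
  edges <- network$edges

  if (length(ids) == 0) {
    return(structure(
      list(membership = tibble::tibble(feature_id = character(0),
                                       community = integer(0)),
           modularity = 0),
      class = "network_partition"))
  }

  # nodes without edges can never merge (gain is -2*a_i*a_j <= 0); keep the
  # agglomeration matrix to the connected part
  connected <- sort(unique(c(edges$from, edges$to)))
  label_of <- stats::setNames(ids, ids)   # node -> community label (a node id)

  if (length(connected) >= 2 && nrow(edges) > 0) {
    k <- length(connected)
    W <- sum(edges$weight)
    E <- matrix(0, k, k, dimnames = list(connected, connected))
    fi <- match(edges$from, connected)
    ti <- match(edges$to, connected)
    E[cbind(fi, ti)] <- edges$weight / (2 * W)
    E[cbind(ti, fi)] <- edges$weight / (2 * W)
    a <- rowSums(E)
    alive <- rep(TRUE, k)
    labels <- connected   # community label = smallest member id

    repeat {
      live <- which(alive)
      if (length(live) < 2) break
      gain <- 2 * (E[live, live, drop = FALSE] -
                     outer(a[live], a[live]))
      gain[E[live, live, drop = FALSE] == 0] <- -Inf  # only connected pairs
      diag(gain) <- -Inf
      best <- max(gain)
      if (best <= 0) break
      # candidate pairs at the maximal gain; break ties lexicographically
      cand <- which(gain == best, arr.ind = TRUE)
      cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
      pair_labels <- cbind(labels[live[cand[, 1]]], labels[live[cand[, 2]]])
      lo <- pmin(pair_labels[, 1], pair_labels[, 2])
      hi <- pmax(pair_labels[, 1], pair_labels[, 2])
      pick <- order(lo, hi)[1]
      i <- live[cand[pick, 1]]
      j <- live[cand[pick, 2]]
      if (labels[j] < labels[i]) { tmp <- i; i <- j; j <- tmp }
      # merge j into i
      E[i, ] <- E[i, ] + E[j, ]
      E[, i] <- E[, i] + E[, j]   # diagonal picks up 2*e_ij, as required
      a[i] <- a[i] + a[j]
      alive[j] <- FALSE
      E[j, ] <- 0
      E[, j] <- 0
      label_of[label_of == labels[j]] <- labels[i]
      labels[j] <- NA
    }
  }

  # dense community ids ordered by smallest member
  comm_labels <- sort(unique(label_of))
  membership <- tibble::tibble(
    feature_id = network$nodes$feature_id,
    community = match(label_of[network$nodes$feature_id], comm_labels) - 1L
  )
  q <- modularity_q(network, stats::setNames(membership$community,
                                             membership$feature_id))
  structure(list(membership = membership, modularity = q),
            class = "network_partition")
}

# Louvain-style multilevel optimisation via igraph, fixed seed; isolated
# nodes are appended as singleton communities with fresh labels.
detect_communities_multilevel <- function(network) {
  edges <- network$edges
  ids <- network$nodes$feature_id
  if (nrow(edges) == 0 || length(ids) == 0) {
    membership <- tibble::tibble(
      feature_id = ids,
      community = if (length(ids)) seq_along(ids) - 1L else integer(0))
    q <- if (length(ids)) modularity_q(network, stats::setNames(
      membership$community, membership$feature_id)) else 0
    return(structure(list(membership = membership, modularity = q),
                     class = "network_partition"))
  }
  connected <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = connected)
  comm <- withr::with_seed(1L, igraph::cluster_louvain(
    g, weights = igraph::E(g)$weight))
  label_of <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  label_of[connected] <- igraph::membership(comm)[connected]
  iso <- is.na(label_of)
  label_of[iso] <- max(label_of, na.rm = TRUE) + seq_len(sum(iso))
  # renumber densely by smallest member
  first_member <- tapply(names(label_of), label_of, min)
  dense <- stats::setNames(order(order(first_member)) - 1L,
                           names(first_member))
  membership <- tibble::tibble(
    feature_id = ids,
    community = unname(dense[as.character(label_of[ids])]))
  q <- modularity_q(network, stats::setNames(membership$community,
                                             membership$feature_id))
  structure(list(membership = membership, modularity = q),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  n_comm <- dplyr::n_distinct(x$membership$community)
  cat(sprintf("<network_partition> %d node(s) in %d communit%s, Q = %.4f\n",
              nrow(x$membership), n_comm, if (n_comm == 1) "y" else "ies",
              x$modularity))
  invisible(x)
}

#' @export
tidy.network_partition <- function(x, ...) {
  x$membership
}

#' Community structure across correlation thresholds
#'
#' Rebuilds the network and partition over a grid of |rho| cutoffs, to
#' surface how sensitive the community structure is to the threshold.
#'
#' @param corr A `correlation_matrix`.
#' @param thresholds Cutoff grid (default `seq(0.3, 0.9, by = 0.1)`).
#' @param min_pairs Minimum complete pairs per edge.
#' @return A tibble with `threshold`, `n_edges`, `n_communities`,
#'   `modularity`.
#' @export
threshold_sweep <- function(corr, thresholds = seq(0.3, 0.9, by = 0.1),
                            min_pairs = 10) {
  purrr::map_dfr(thresholds, function(th) {
    net <- build_network(corr, threshold = th, min_pairs = min_pairs)
    part <- detect_communities(net)
    tibble::tibble(
      threshold = th,
      n_edges = nrow(net$edges),
      n_communities = dplyr::n_distinct(part$membership$community),
      modularity = part$modularity
    )
  })
}
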