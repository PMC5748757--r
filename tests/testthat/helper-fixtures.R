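# Shared fixtures and independent oracles, all built in code.

# A small study configuration that keeps forest fits fast.
tiny_config <- function(seed = 1L, ...) {
  args <- list(
    n_subjects_per_group = 2, n_days = 9,
    n_fecal_metabolites = 20, n_urinary_metabolites = 15,
    n_taxa = 12, n_elements = 5,
    n_planted = 4, n_blocks = 2,
    seed = seed
  )
  do.call(study_config, utils::modifyList(args, list(...)))
}

# A random feature table with optional missing cells.
random_table <- function(n = 8, p = 6, na_frac = 0, seed = 1L) {
  withr::with_seed(seed, {
    vals <- matrix(exp(rnorm(n * p)), n, p)
    if (na_frac > 0) vals[sample(length(vals), round(na_frac * n * p))] <- NA
    feature_table(
      vals,
      tibble::tibble(
        sample_id = sprintf("s%02d", seq_len(n)),
        subject = sprintf("m%02d", rep_len(1:4, n)),
        group = rep_len(c("cellulose", "P_aquilinum"), n),
        period = rep_len(c("pre", "during", "post"), n),
        day = rep_len(1:9, n)
      ),
      tibble::tibble(
        feature_id = sprintf("fm:f%02d", seq_len(p)),
        assay = "fecal_metabolite",
        display_name = sprintf("feat_%02d", seq_len(p))
      )
    )
  })
}

# Build a correlation_network directly from an edge list (unit weights by
# default); nodes may include isolated ones.
edge_network <- function(edges, nodes = NULL, weights = 1) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges) <- c("from", "to")
  w <- rep_len(weights, nrow(edges))
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  ord <- order(edges$from, edges$to)
  nodes <- sort(unique(c(edges$from, edges$to, nodes)))
  structure(
    list(
      nodes = tibble::tibble(feature_id = nodes, assay = NA_character_),
      edges = tibble::tibble(from = edges$from[ord], to = edges$to[ord],
                             weight = w[ord], rho = w[ord],
                             sign = 1L),
      threshold = 0, min_pairs = 0
    ),
    class = "correlation_network"
  )
}

# Independent modularity implementation (edge-list form), used as an oracle
# against the package's modularity_q and detect_communities.
oracle_modularity <- function(edges, membership) {
  if (nrow(edges) == 0) return(0)
  W <- sum(edges$weight)
  comm <- membership
  intra <- sum(edges$weight[comm[edges$from] == comm[edges$to]])
  strength <- tapply(
    c(edges$weight, edges$weight), c(edges$from, edges$to), sum)
  q <- 0
  for (c_lab in unique(comm)) {
    members <- names(comm)[comm == c_lab]
    w_c <- sum(edges$weight[comm[edges$from] == c_lab &
                              comm[edges$to] == c_lab])
    s_c <- sum(strength[names(strength) %in% members])
    q <- q + w_c / W - (s_c / (2 * W))^2
  }
  q
}

# Enumerate all set partitions of n items (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, k) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible(NULL))
    }
    for (v in 0:(k + 1)) {
      recurse(c(prefix, v), max(k, v))
    }
  }
  recurse(integer(0), -1L)
  out
}

# Exhaustive-maximum modularity over all partitions of the network's
# connected nodes (isolated nodes kept as singletons).
exhaustive_best_q <- function(network) {
  edges <- network$edges
  nodes <- sort(unique(c(edges$from, edges$to)))
  best <- -Inf
  best_part <- NULL
  for (p in all_partitions(length(nodes))) {
    memb <- stats::setNames(p, nodes)
    q <- oracle_modularity(edges, memb)
    if (q > best) {
      best <- q
      best_part <- memb
    }
  }
  list(q = best, membership = best_part)
}

# Random connected graph with n nodes (edge probability prob, weights in
# [0.2, 1]); resamples until connected.
random_connected_graph <- function(n, prob = 0.5, seed = 1L) {
  withr::with_seed(seed, {
    repeat {
      pairs <- utils::combn(sprintf("n%02d", seq_len(n)), 2)
      keep <- stats::runif(ncol(pairs)) < prob
      if (!any(keep)) next
      edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep])
      g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = sprintf("n%02d",
                                                            seq_len(n)))
      if (igraph::is_connected(g)) {
        return(edge_network(edges,
                            weights = round(stats::runif(nrow(edges),
                                                         0.2, 1), 3)))
      }
    }
  })
}

# Two triangles joined by one bridge edge, unit weights; the greedy optimum
# is the two triangles with Q = 5/14.
bridge_graph <- function() {
  edge_network(rbind(
    c("a1", "a2"), c("a1", "a3"), c("a2", "a3"),
    c("b1", "b2"), c("b1", "b3"), c("b2", "b3"),
    c("a1", "b1")
  ))
}

# Forge a partition object for overlay tests.
forge_partition <- function(membership) {
  structure(
    list(membership = tibble::tibble(feature_id = names(membership),
                                     community = as.integer(membership)),
         modularity = NA_real_),
    class = "network_partition"
  )
}

expect_tibble_equal <- function(a, b, tolerance = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tolerance)
}
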