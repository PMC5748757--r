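test_that("Spearman rho matches the closed form on a 3-point example", {
  m <- cbind(x = c(1, 2, 3), y = c(3, 1, 2))
  # closed form: 1 - 6*sum(d^2)/(n(n^2-1)) = 1 - 36/24 = -0.5
  corr3 <- spearman_matrix(m)
  expect_equal(corr3$rho["x", "y"], -0.5, tolerance = 1e-12)
  expect_equal(corr3$n_pairs["x", "y"], 3)
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  withr::with_seed(1, {
    x <- rnorm(25)
    y <- rnorm(25)
  })
  a <- spearman_matrix(cbind(x = x, y = y))$rho["x", "y"]
  b <- spearman_matrix(cbind(x = exp(x), y = y))$rho["x", "y"]
  c_ <- spearman_matrix(cbind(x = x^3, y = 1 / (1 + exp(-y))))$rho["x", "y"]
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(a, c_, tolerance = 1e-12)
  expect_equal(spearman_matrix(cbind(x = x, y = exp(x)))$rho["x", "y"], 1)
})

test_that("tied data match the Pearson-on-midranks oracle exactly", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      x <- sample(1:5, 30, replace = TRUE)
      y <- sample(1:5, 30, replace = TRUE)
    })
    got <- spearman_matrix(cbind(x = x, y = y))$rho["x", "y"]
    oracle <- cor(rank(x), rank(y))   # Pearson on midranks
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("pairwise-complete correlations agree with the generic path", {
  withr::with_seed(3, {
    m <- matrix(sample(1:8, 25 * 10, TRUE) + rnorm(250, sd = 0.01), 25, 10)
    m[sample(length(m), 50)] <- NA
    colnames(m) <- sprintf("f%02d", 1:10)
  })
  got <- spearman_matrix(m)
  ref <- suppressWarnings(
    cor(m, method = "spearman", use = "pairwise.complete.obs"))
  diag(ref) <- 1
  expect_equal(got$rho, ref, tolerance = 1e-12)
  expect_equal(got$n_pairs, crossprod(!is.na(m)), ignore_attr = TRUE)
})

test_that("build_network filters edges exactly as a brute-force scan", {
  withr::with_seed(4, m <- matrix(rnorm(40 * 8), 40, 8))
  colnames(m) <- sprintf("f%d", 1:8)
  corr <- spearman_matrix(m)
  net <- build_network(corr, threshold = 0.2, min_pairs = 10)
  expected <- list()
  ids <- colnames(m)
  for (i in 1:7) for (j in (i + 1):8) {
    if (abs(corr$rho[i, j]) >= 0.2 && corr$n_pairs[i, j] >= 10) {
      expected[[length(expected) + 1]] <-
        c(min(ids[i], ids[j]), max(ids[i], ids[j]))
    }
  }
  key <- vapply(expected, paste, character(1), collapse = "|")
  expect_setequal(paste(net$edges$from, net$edges$to, sep = "|"), key)
  expect_true(all(net$edges$weight >= 0.2))
  expect_equal(net$edges$weight, abs(net$edges$rho))

  # boundary thresholds
  expect_equal(nrow(build_network(corr, threshold = 1)$edges), 0L)
  full <- build_network(corr, threshold = 0, min_pairs = 10)
  expect_equal(nrow(full$edges), choose(8, 2))
  expect_equal(nrow(full$nodes), 8L)
})

test_that("modularity matches hand computation and the igraph oracle", {
  net <- bridge_graph()
  triangles <- c(a1 = 0, a2 = 0, a3 = 0, b1 = 1, b2 = 1, b3 = 1)
  expect_equal(modularity_q(net, triangles), 5 / 14, tolerance = 1e-12)
  expect_equal(modularity_q(net, stats::setNames(rep(0, 6), names(triangles))),
               0, tolerance = 1e-12)

  for (seed in 1:10) {
    net <- random_connected_graph(6, seed = seed)
    memb <- withr::with_seed(seed, sample(0:2, 6, replace = TRUE))
    names(memb) <- net$nodes$feature_id
    got <- modularity_q(net, memb)
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes$feature_id)
    ref <- igraph::modularity(g, memb[igraph::V(g)$name] + 1,
                              weights = igraph::E(g)$weight)
    expect_equal(got, ref, tolerance = 1e-12)
    expect_equal(got, oracle_modularity(net$edges, memb), tolerance = 1e-12)
  }
})

test_that("modularity rejects assignments that miss nodes", {
  net <- bridge_graph()
  expect_error(modularity_q(net, c(a1 = 0)), "does not cover")
})

test_that("greedy community detection resolves the two-triangle bridge", {
  part <- detect_communities(bridge_graph())
  memb <- stats::setNames(part$membership$community,
                          part$membership$feature_id)
  expect_equal(length(unique(memb)), 2L)
  expect_equal(length(unique(memb[c("a1", "a2", "a3")])), 1L)
  expect_equal(length(unique(memb[c("b1", "b2", "b3")])), 1L)
  expect_equal(part$modularity, 5 / 14, tolerance = 1e-12)

  # exhaustive search confirms this is the global optimum
  best <- exhaustive_best_q(bridge_graph())
  expect_equal(part$modularity, best$q, tolerance = 1e-12)
})

test_that("disconnected components never merge and singletons persist", {
  net <- edge_network(rbind(c("a", "b"), c("c", "d")), nodes = c("e"))
  part <- detect_communities(net)
  memb <- stats::setNames(part$membership$community,
                          part$membership$feature_id)
  expect_equal(memb[["a"]], memb[["b"]])
  expect_equal(memb[["c"]], memb[["d"]])
  expect_equal(length(unique(memb)), 3L)
  expect_equal(part$modularity,
               modularity_q(net, memb), tolerance = 1e-12)
})

test_that("the empty network yields an empty partition with Q = 0", {
  net <- structure(
    list(nodes = tibble::tibble(feature_id = character(0),
                                assay = character(0)),
         edges = tibble::tibble(from = character(0), to = character(0),
                                weight = numeric(0), rho = numeric(0),
                                sign = integer(0)),
         threshold = 0.6, min_pairs = 10),
    class = "correlation_network")
  part <- detect_communities(net)
  expect_equal(nrow(part$membership), 0L)
  expect_equal(part$modularity, 0)
})

test_that("greedy Q never exceeds the exhaustive optimum on small graphs", {
  for (seed in 1:15) {
    n <- 4 + (seed %% 4)
    net <- random_connected_graph(n, prob = 0.55, seed = 100 + seed)
    part <- detect_communities(net)
    best <- exhaustive_best_q(net)
    expect_lte(part$modularity, best$q + 1e-12)
    expect_equal(part$modularity,
                 modularity_q(net, stats::setNames(part$membership$community,
                                                   part$membership$feature_id)),
                 tolerance = 1e-12)
  }
})

test_that("planted two-block graphs are recovered exactly", {
  for (seed in 1:5) {
    blocks <- list(sprintf("a%d", 1:4), sprintf("b%d", 1:4))
    within <- do.call(rbind, lapply(blocks, function(b) t(utils::combn(b, 2))))
    between <- cbind(blocks[[1]], blocks[[2]])
    edges <- rbind(within, between)
    net <- edge_network(edges, weights = c(rep(1, nrow(within)),
                                           rep(0.1, nrow(between))))
    part <- detect_communities(net)
    memb <- stats::setNames(part$membership$community,
                            part$membership$feature_id)
    expect_equal(length(unique(memb[blocks[[1]]])), 1L)
    expect_equal(length(unique(memb[blocks[[2]]])), 1L)
    expect_equal(length(unique(memb)), 2L)
  }
})

test_that("community structure is invariant under node relabeling", {
  net <- random_connected_graph(7, seed = 42)
  part <- detect_communities(net)
  relabel <- stats::setNames(sprintf("zz%02d", 7:1), net$nodes$feature_id)
  net2 <- net
  net2$nodes$feature_id <- unname(relabel[net$nodes$feature_id])
  net2$edges$from <- unname(relabel[net$edges$from])
  net2$edges$to <- unname(relabel[net$edges$to])
  swap <- net2$edges$from > net2$edges$to
  tmp <- net2$edges$from[swap]
  net2$edges$from[swap] <- net2$edges$to[swap]
  net2$edges$to[swap] <- tmp
  part2 <- detect_communities(net2)
  m1 <- stats::setNames(part$membership$community, part$membership$feature_id)
  m2 <- stats::setNames(part2$membership$community,
                        part2$membership$feature_id)
  m2_mapped <- m2[unname(relabel[names(m1)])]
  # same partition up to label permutation
  expect_equal(length(unique(paste(m1, m2_mapped))),
               length(unique(m1)))
  expect_equal(part$modularity, part2$modularity, tolerance = 1e-12)
})

test_that("returned Q dominates the trivial partitions", {
  for (seed in 1:5) {
    net <- random_connected_graph(7, seed = 200 + seed)
    part <- detect_communities(net)
    ids <- net$nodes$feature_id
    singletons <- stats::setNames(seq_along(ids) - 1L, ids)
    one <- stats::setNames(rep(0L, length(ids)), ids)
    expect_gte(part$modularity, modularity_q(net, singletons) - 1e-12)
    expect_gte(part$modularity, modularity_q(net, one) - 1e-12)
  }
})

test_that("threshold sweep reports edges, communities and Q per cutoff", {
  withr::with_seed(5, m <- matrix(rnorm(30 * 6), 30, 6))
  colnames(m) <- sprintf("f%d", 1:6)
  sweep_tbl <- threshold_sweep(spearman_matrix(m),
                               thresholds = c(0, 0.3, 1), min_pairs = 5)
  expect_equal(nrow(sweep_tbl), 3L)
  expect_true(all(diff(sweep_tbl$n_edges) <= 0))
  expect_equal(sweep_tbl$n_edges[1], choose(6, 2))
})

test_that("the multilevel alternative also resolves the bridge graph", {
  part <- detect_communities(bridge_graph(), method = "multilevel")
  memb <- stats::setNames(part$membership$community,
                          part$membership$feature_id)
  expect_equal(length(unique(memb)), 2L)
  expect_equal(length(unique(memb[c("a1", "a2", "a3")])), 1L)
  expect_equal(part$modularity, 5 / 14, tolerance = 1e-12)
  # isolated nodes stay singletons here too
  net <- edge_network(rbind(c("a", "b")), nodes = "z")
  p2 <- detect_communities(net, method = "multilevel")
  expect_equal(dplyr::n_distinct(p2$membership$community), 2L)
})
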