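test_that("overlay selects exactly the communities holding important factors", {
  part <- forge_partition(c(a = 0, b = 0, c = 1, d = 1, e = 2))

  none <- overlay_modules(part, c("x", "y"))
  expect_length(none$selected_communities, 0)
  expect_setequal(none$unplaced, c("x", "y"))

  all_sel <- overlay_modules(part, c("a", "b", "c", "d", "e"))
  expect_equal(all_sel$selected_communities, 0:2)

  some <- overlay_modules(part, c("b", "e", "zz"))
  expect_equal(some$selected_communities, c(0L, 2L))
  expect_equal(some$members_of[["0"]], c("a", "b"))
  expect_equal(some$important_in[["0"]], "b")
  expect_equal(some$unplaced, "zz")
})

test_that("random overlays equal a brute-force membership scan", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      ids <- sprintf("f%02d", 1:12)
      memb <- stats::setNames(sample(0:3, 12, replace = TRUE), ids)
      important <- sample(c(ids, sprintf("x%d", 1:3)), 5)
    })
    ov <- overlay_modules(forge_partition(memb), important)
    expected_sel <- sort(unique(memb[intersect(important, ids)]))
    expect_equal(ov$selected_communities, as.integer(unname(expected_sel)))
    for (c_lab in names(ov$members_of)) {
      expect_setequal(ov$members_of[[c_lab]],
                      names(memb)[memb == as.integer(c_lab)])
    }
    expect_setequal(ov$unplaced, setdiff(important, ids))
    # every important factor is in exactly one community or unplaced
    placed <- unlist(ov$important_in, use.names = FALSE)
    expect_setequal(c(placed, ov$unplaced), important)
    expect_equal(anyDuplicated(placed), 0L)
  }
})

test_that("Mann-Whitney matches its exact and approximate contracts", {
  # 1 favourable arrangement of C(6,3) = 20, doubled
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1, tolerance = 1e-12)
  expect_equal(mw$method, "exact")

  ident <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(ident$p, 1)

  expect_error(mann_whitney_u(c(1), c(2, 3)), ">= 2 observations")
})

test_that("the normal approximation agrees with wilcox.test", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      x <- rnorm(15)
      y <- rnorm(18, mean = 0.5)
    })
    mw <- mann_whitney_u(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(mw$U, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mw$p, ref$p.value, tolerance = 1e-12)
    expect_equal(mw$method, "normal")
  }
  # tie-corrected variance path
  withr::with_seed(30, {
    x <- sample(1:4, 20, TRUE)
    y <- sample(2:5, 20, TRUE)
  })
  mw <- mann_whitney_u(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  expect_equal(mw$p, ref$p.value, tolerance = 1e-12)
})

test_that("exact p-values match a small permutation enumeration", {
  x <- c(0.3, 1.2, 2.2)
  y <- c(0.6, 1.9, 2.8, 3.4)
  mw <- mann_whitney_u(x, y)
  pooled <- c(x, y)
  combos <- utils::combn(7, 3)
  u_all <- apply(combos, 2, function(ix) {
    r <- rank(pooled)
    sum(r[ix]) - 3 * 4 / 2
  })
  mu <- 3 * 4 / 2
  p_perm <- min(1, 2 * min(mean(u_all <= mw$U), mean(u_all >= mw$U)))
  expect_equal(mw$p, p_perm, tolerance = 1e-12)
})

test_that("Holm adjustment follows the step-down formula", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06),
               tolerance = 1e-12)
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(0.03, 4)), rep(0.12, 4), tolerance = 1e-12)
  expect_equal(holm_adjust(numeric(0)), numeric(0))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(holm_adjust(c(0.5, -0.1)), "0, 1")
})

test_that("Holm matches p.adjust and the stepwise-rejection oracle", {
  for (seed in 1:25) {
    p <- withr::with_seed(seed, runif(1 + seed %% 8))
    adj <- holm_adjust(p)
    expect_equal(adj, stats::p.adjust(p, "holm"), tolerance = 1e-15)

    # stepwise oracle: reject while p_(j) <= alpha / (m - j + 1)
    for (alpha in c(0.01, 0.05, 0.2)) {
      m <- length(p)
      ord <- order(p)
      rejected_oracle <- logical(m)
      for (j in seq_len(m)) {
        if (p[ord[j]] <= alpha / (m - j + 1)) {
          rejected_oracle[ord[j]] <- TRUE
        } else break
      }
      expect_equal(adj <= alpha, rejected_oracle)
    }
  }
})

test_that("BH <= Holm <= Bonferroni entrywise", {
  for (seed in 1:25) {
    p <- withr::with_seed(100 + seed, runif(2 + seed %% 10))
    holm <- holm_adjust(p)
    expect_true(all(stats::p.adjust(p, "BH") <= holm + 1e-15))
    expect_true(all(holm <= stats::p.adjust(p, "bonferroni") + 1e-15))
    expect_true(all(holm >= p - 1e-15))
    expect_true(all(holm <= 1))
  }
})

# One planted factor, three groups, n per group, iid noise; group 3 shifted.
planted_test_table <- function(n_per_group = 24, delta = 2, seed = 1) {
  withr::with_seed(seed, {
    groups <- rep(c("cellulose", "P_aquilinum", "M_struthiopteris"),
                  each = n_per_group)
    v <- rnorm(length(groups))
    v[groups == "M_struthiopteris"] <- v[groups == "M_struthiopteris"] + delta
    vals <- cbind("fm:hit" = exp(v), "fm:null" = exp(rnorm(length(groups))))
    feature_table(
      vals,
      tibble::tibble(sample_id = sprintf("s%03d", seq_along(groups)),
                     subject = sprintf("m%03d", seq_along(groups)),
                     group = groups, period = "during",
                     day = 7L),
      tibble::tibble(feature_id = colnames(vals), assay = "fecal_metabolite",
                     display_name = c("hit", "null"))
    )
  })
}

test_that("module factor tests flag a strong planted effect at p < 0.001", {
  part <- forge_partition(c("fm:hit" = 0, "fm:null" = 1))
  hits <- vapply(1:20, function(s) {
    tab <- planted_test_table(n_per_group = 24, delta = 2, seed = s)
    ov <- overlay_modules(part, "fm:hit")
    res <- test_module_factors(tab, ov)
    min(res$p_holm[res$group1 == "M_struthiopteris" |
                     res$group2 == "M_struthiopteris"])
  }, numeric(1))
  expect_gte(mean(hits < 0.001), 0.9)
})

test_that("test results carry consistent columns, stars and families", {
  tab <- planted_test_table(seed = 3)
  part <- forge_partition(c("fm:hit" = 0, "fm:null" = 0))
  ov <- overlay_modules(part, c("fm:hit", "fm:null"))
  res <- test_module_factors(tab, ov)
  expect_equal(nrow(res), 2 * 3)   # 2 factors x 3 group pairs
  expect_true(all(res$p_holm >= res$p - 1e-15))
  expect_true(all(res$p_holm <= 1))
  expect_equal(res$stars[res$p_holm < 0.001],
               rep("***", sum(res$p_holm < 0.001)))
  expect_true(all(res$stars[res$p_holm >= 0.05] == ""))
  # family scope: per-factor families adjust with m = 3
  res_pf <- test_module_factors(tab, ov, family = "per_factor")
  for (f in c("fm:hit", "fm:null")) {
    idx <- res_pf$feature_id == f
    expect_equal(res_pf$p_holm[idx], holm_adjust(res_pf$p[idx]),
                 tolerance = 1e-12)
  }
})

test_that("empty overlays give an empty, well-typed result", {
  tab <- planted_test_table(seed = 4)
  ov <- overlay_modules(forge_partition(c("fm:hit" = 0)), "zz:none")
  res <- test_module_factors(tab, ov)
  expect_s3_class(res, "group_test_result")
  expect_equal(nrow(res), 0L)
})

test_that("factors lacking observations are skipped with a warning", {
  tab <- planted_test_table(n_per_group = 3, seed = 5)
  tab$values[tab$sample_meta$group == "cellulose", "fm:hit"] <- NA
  ov <- overlay_modules(forge_partition(c("fm:hit" = 0)), "fm:hit")
  w <- testthat::capture_warnings(res <- test_module_factors(tab, ov))
  expect_match(w, "< 2 observations", all = TRUE)
  expect_length(w, 2)   # both cellulose pairs skipped
  expect_true(all(res$group1 != "cellulose" & res$group2 != "cellulose"))
})

test_that("module reports enumerate members, assays and edges", {
  sim <- generate_study(tiny_config(seed = 6))
  tab <- sim$table
  ids <- tab$feature_meta$feature_id
  five <- c(ids[1:3], ids[c(22, 30)])   # fecal + urinary mix
  memb <- stats::setNames(c(0, 0, 0, 0, 0), five)
  part <- forge_partition(memb)
  net <- edge_network(t(utils::combn(five, 2)), weights = 0.7)
  net$nodes$assay <- tab$feature_meta$assay[match(net$nodes$feature_id, ids)]
  ov <- overlay_modules(part, five[1])
  res <- suppressWarnings(test_module_factors(tab, ov))
  imp <- tibble::tibble(feature_id = ids, mda = 0, rank = 1L)
  rep_ <- module_report(ov, res, net, imp, tab)
  expect_length(rep_$modules, 1)
  mod <- rep_$modules[[1]]
  expect_equal(nrow(mod$members), 5L)
  expect_equal(nrow(mod$edges), choose(5, 2))
  expect_setequal(unique(mod$members$assay),
                  c("fecal_metabolite", "urinary_metabolite"))
  expect_equal(sum(mod$members$is_important), 1L)

  dir <- withr::local_tempdir()
  write_module_report(rep_, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  parsed <- jsonlite::read_json(file.path(dir, "report.json"),
                                simplifyVector = TRUE)
  expect_equal(length(parsed$modules), 1L)
})

test_that("the omnibus gate drops factors without any group signal", {
  tab <- planted_test_table(seed = 8)
  part <- forge_partition(c("fm:hit" = 0, "fm:null" = 0))
  ov <- overlay_modules(part, c("fm:hit", "fm:null"))
  res <- test_module_factors(tab, ov, omnibus_alpha = 0.01)
  expect_true("fm:hit" %in% res$feature_id)
  expect_false("fm:null" %in% res$feature_id)
})
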