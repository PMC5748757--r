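#' Overlay important factors onto network communities
#'
#' Selects every community that contains at least one important factor and
#' enumerates its full membership; important factors that are not nodes of
#' the partition are reported as unplaced.
#'
#' @param partition A `network_partition` from [detect_communities()].
#' @param important Character vector of important feature ids.
#' @return A `module_overlay`: `selected_communities` (integer labels),
#'   `members_of` and `important_in` (lists keyed by community label) and
#'   `unplaced` (character vector).
#' @export
overlay_modules <- function(partition, important) {
  stopifnot(inherits(partition, "network_partition"))
  membership <- partition$membership
  important <- unique(as.character(important))
  placed <- important[important %in% membership$feature_id]
  unplaced <- setdiff(important, placed)

  selected <- sort(unique(
    membership$community[membership$feature_id %in% placed]))
  members_of <- lapply(selected, function(c) {
    sort(membership$feature_id[membership$community == c])
  })
  important_in <- lapply(selected, function(c) {
    sort(intersect(placed,
                   membership$feature_id[membership$community == c]))
  })
  names(members_of) <- names(important_in) <- as.character(selected)

  structure(
    list(selected_communities = selected, members_of = members_of,
         important_in = important_in, unplaced = unplaced),
    class = "module_overlay"
  )
}

#' @export
print.module_overlay <- function(x, ...) {
  cat(sprintf("<module_overlay> %d selected communit%s, %d unplaced factor(s)\n",
              length(x$selected_communities),
              if (length(x$selected_communities) == 1) "y" else "ies",
              length(x$unplaced)))
  for (c in names(x$members_of)) {
    cat(sprintf("  community %s: %d member(s), %d important\n", c,
                length(x$members_of[[c]]), length(x$important_in[[c]])))
  }
  invisible(x)
}

#' Mann-Whitney U test (two-sided)
#'
#' `U` counts the pairs with `x > y` (ties count one half). The two-sided
#' p-value is exact (enumeration over rank arrangements) when
#' `length(x) + length(y) <= 12` and there are no ties, and otherwise uses
#' the normal approximation with tie-corrected variance and continuity
#' correction.
#'
#' @param x,y Numeric samples, each with at least 2 observations.
#' @return A list with `U`, `p` and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort("each group needs >= 2 observations")

  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)

  if (n1 + n2 <= 12 && !has_ties) {
    # exact two-sided p from the null permutation distribution of U
    lower <- pwilcox(U, n1, n2)
    upper <- 1 - pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1   # all observations tied: no evidence either way
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

#' Holm step-down adjustment
#'
#' Sort the m raw p-values ascending; the i-th adjusted value is
#' `max_{j <= i} ((m - j + 1) * p_(j))`, capped at 1, returned in the input
#' order. Controls the family-wise error rate; uniformly less conservative
#' than Bonferroni and more conservative than Benjamini-Hochberg.
#'
#' @param pvals Raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order and length.
#' @export
holm_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  ord <- order(pvals)
  adj <- cummax((m - seq_len(m) + 1) * pvals[ord])
  pmin(adj, 1)[order(ord)]
}

significance_stars <- function(p_adj) {
  dplyr::case_when(
    p_adj < 0.001 ~ "***",
    p_adj < 0.01 ~ "**",
    p_adj < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Test module factors across treatment groups
#'
#' For every important factor inside a selected community, compares its
#' values between each pair of treatment groups with a two-sided
#' Mann-Whitney test and applies the Holm correction. By default the
#' comparison uses during- and post-period samples and the Holm family is
#' all (factor x group-pair) tests of the run; `family = "per_factor"`
#' restricts each family to one factor's pairs.
#'
#' @param table A [feature_table()] holding the factor values.
#' @param overlay A `module_overlay` from [overlay_modules()].
#' @param periods Periods whose samples enter the tests (default
#'   `c("during", "post")`).
#' @param family Holm family scope: `"all"` (default) or `"per_factor"`.
#' @param omnibus_alpha When set, a Kruskal-Wallis omnibus test gates each
#'   factor: pairwise comparisons run only when its omnibus p-value is
#'   below this level. `NULL` (default) disables the gate.
#' @return A `group_test_result` tibble with one row per (factor, group
#'   pair): `feature_id`, `community`, `group1`, `group2`, `n1`, `n2`, `U`,
#'   `p`, `p_holm`, `stars`.
#' @export
test_module_factors <- function(table, overlay,
                                periods = c("during", "post"),
                                family = c("all", "per_factor"),
                                omnibus_alpha = NULL) {
  stopifnot(inherits(table, "feature_table"),
            inherits(overlay, "module_overlay"))
  family <- match.arg(family)

  meta <- table$sample_meta
  groups <- sort(unique(meta$group))
  if (length(groups) < 2) abort("need >= 2 treatment groups")
  pairs <- utils::combn(groups, 2)

  factors <- tibble::tibble(
    feature_id = unlist(overlay$important_in, use.names = FALSE),
    community = rep(as.integer(names(overlay$important_in)),
                    lengths(overlay$important_in))
  )
  empty <- tibble::tibble(
    feature_id = character(0), community = integer(0),
    group1 = character(0), group2 = character(0),
    n1 = integer(0), n2 = integer(0), U = numeric(0), p = numeric(0),
    p_holm = numeric(0), stars = character(0)
  )
  class(empty) <- c("group_test_result", class(empty))
  if (nrow(factors) == 0) return(empty)

  in_period <- meta$period %in% periods
  rows <- purrr::pmap_dfr(factors, function(feature_id, community) {
    v <- table$values[, feature_id]
    if (!is.null(omnibus_alpha)) {
      ok <- in_period & !is.na(v)
      kw <- stats::kruskal.test(v[ok], factor(meta$group[ok]))
      if (kw$p.value >= omnibus_alpha) return(NULL)
    }
    purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      g1 <- pairs[1, k]
      g2 <- pairs[2, k]
      x <- v[in_period & meta$group == g1]
      y <- v[in_period & meta$group == g2]
      x <- x[!is.na(x)]
      y <- y[!is.na(y)]
      if (length(x) < 2 || length(y) < 2) {
        warn(sprintf(
          "skipping %s for %s vs %s: a group has < 2 observations",
          feature_id, g1, g2))
        return(NULL)
      }
      mw <- mann_whitney_u(x, y)
      tibble::tibble(
        feature_id = feature_id, community = community,
        group1 = g1, group2 = g2,
        n1 = length(x), n2 = length(y),
        U = mw$U, p = mw$p
      )
    })
  })
  if (nrow(rows) == 0) return(empty)

  rows$p_holm <- if (family == "all") {
    holm_adjust(rows$p)
  } else {
    stats::ave(rows$p, rows$feature_id, FUN = holm_adjust)
  }
  rows$stars <- significance_stars(rows$p_holm)
  class(rows) <- c("group_test_result", class(rows))
  rows
}

#' Assemble the per-module report
#'
#' One record per selected community: its members with assay class, display
#' name and importance rank, the group-comparison tests of its important
#' factors, and its internal edge list.
#'
#' @param overlay A `module_overlay`.
#' @param tests A `group_test_result` from [test_module_factors()].
#' @param network The `correlation_network` the partition was computed on.
#' @param importance An `importance_result` from [importance_mda()].
#' @param table The [feature_table()] supplying feature metadata.
#' @return A `module_report`: list with `modules` (list per community:
#'   `community`, `members`, `tests`, `edges`), `unplaced` and
#'   `n_significant` (factors with Holm-adjusted p < 0.05).
#' @export
module_report <- function(overlay, tests, network, importance, table) {
  stopifnot(inherits(overlay, "module_overlay"))
  fm <- table$feature_meta
  modules <- lapply(names(overlay$members_of), function(c) {
    members <- overlay$members_of[[c]]
    idx <- match(members, fm$feature_id)
    member_tbl <- tibble::tibble(
      feature_id = members,
      assay = fm$assay[idx],
      display_name = fm$display_name[idx],
      mda = importance$mda[match(members, importance$feature_id)],
      rank = importance$rank[match(members, importance$feature_id)],
      is_important = members %in% overlay$important_in[[c]]
    )
    edges <- network$edges[network$edges$from %in% members &
                             network$edges$to %in% members, , drop = FALSE]
    list(
      community = as.integer(c),
      members = member_tbl,
      tests = tests[tests$community == as.integer(c), , drop = FALSE],
      edges = edges
    )
  })
  names(modules) <- names(overlay$members_of)
  structure(
    list(modules = modules, unplaced = overlay$unplaced,
         n_significant = if (nrow(tests) > 0) {
           dplyr::n_distinct(tests$feature_id[tests$p_holm < 0.05])
         } else 0L),
    class = "module_report"
  )
}

#' @export
print.module_report <- function(x, ...) {
  cat(sprintf("<module_report> %d module(s), %d significant factor(s)\n",
              length(x$modules), x$n_significant))
  for (m in x$modules) {
    cat(sprintf("  community %d: %d member(s) [%s], %d important\n",
                m$community, nrow(m$members),
                paste(unique(m$members$assay), collapse = ", "),
                sum(m$members$is_important)))
  }
  if (length(x$unplaced) > 0) {
    cat("  unplaced:", paste(x$unplaced, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a module report to disk
#'
#' Writes `report.json` (full report), `module_members.tsv` and
#' `module_tests.tsv` under `dir`.
#'
#' @param report A `module_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_module_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(
      modules = lapply(report$modules, function(m) {
        list(community = m$community, members = m$members,
             tests = m$tests, edges = m$edges)
      }),
      unplaced = report$unplaced,
      n_significant = report$n_significant
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows"
  )
  members <- purrr::map_dfr(report$modules, function(m) {
    dplyr::mutate(m$members, community = m$community, .before = 1)
  })
  readr::write_tsv(members, file.path(dir, "module_members.tsv"))
  tests <- purrr::map_dfr(report$modules, function(m) tibble::as_tibble(m$tests))
  readr::write_tsv(tests, file.path(dir, "module_tests.tsv"))
  invisible(dir)
}
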