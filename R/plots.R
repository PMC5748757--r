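#' @export
autoplot.gutnet_pca <- function(object, colour = "group", shape = "period",
                                ...) {
  d <- tidy(object)
  if (is.null(object$sample_meta)) {
    colour <- NULL
    shape <- NULL
  }
  v <- 100 * object$explained_variance_ratio
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(ggplot2::aes(
      colour = if (!is.null(colour)) .data[[colour]],
      shape = if (!is.null(shape)) .data[[shape]]), size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", v[1]),
      y = sprintf("PC2 (%.1f%%)", v[2]),
      colour = colour, shape = shape,
      title = "Principal component analysis"
    ) +
    ggplot2::theme_minimal()
  p
}

# MDS plot of a pipeline run, points labelled by the RF classes
autoplot_mds_run <- function(run) {
  d <- tidy(run$mds)
  d$class <- as.character(run$model$labels)[
    match(d$sample_id, rownames(run$mds$coordinates))]
  ggplot2::ggplot(d, ggplot2::aes(.data$MDS1, .data$MDS2,
                                  colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = "MDS of random-forest proximities") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gutnet_mds <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$MDS1, .data$MDS2)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = "Classical MDS") +
    ggplot2::theme_minimal()
}

#' Bar chart of the top-k important factors
#'
#' @param importance An `importance_result` from [importance_mda()].
#' @param k Number of factors displayed (default 30).
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, k = 30) {
  ids <- top_factors(importance, k = min(k, nrow(importance)))
  d <- tibble::as_tibble(unclass(importance))
  d <- d[match(ids, d$feature_id), ]
  d$feature_id <- factor(d$feature_id, levels = rev(ids))
  ggplot2::ggplot(d, ggplot2::aes(.data$mda, .data$feature_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Mean decrease in accuracy", y = NULL,
                  title = sprintf("Top %d important factors", length(ids))) +
    ggplot2::theme_minimal()
}

#' Boxplots of factor values per treatment group
#'
#' One panel per factor, during/post samples, with Holm-corrected
#' significance stars between group pairs when a test result is supplied.
#'
#' @param table A [feature_table()].
#' @param feature_ids Factors to display.
#' @param tests Optional `group_test_result` supplying stars.
#' @param periods Periods included (default during/post).
#' @return A ggplot object.
#' @export
plot_factor_boxes <- function(table, feature_ids, tests = NULL,
                              periods = c("during", "post")) {
  stopifnot(inherits(table, "feature_table"))
  d <- tidy.feature_table(table)
  d <- d[d$feature_id %in% feature_ids & d$period %in% periods &
           !is.na(d$value), ]
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$value,
                                       fill = .data$group)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(ggplot2::vars(.data$display_name),
                        scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none",
                   axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
  if (!is.null(tests)) {
    lab <- tests[tests$feature_id %in% feature_ids & tests$stars != "", ]
    if (nrow(lab) > 0) {
      lab$display_name <- table$feature_meta$display_name[
        match(lab$feature_id, table$feature_meta$feature_id)]
      lab$label <- sprintf("%s vs %s %s", lab$group1, lab$group2, lab$stars)
      caption <- paste(unique(sprintf("%s: %s", lab$display_name, lab$label)),
                       collapse = "; ")
      p <- p + ggplot2::labs(caption = caption)
    }
  }
  p
}
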