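#' Plot an event-rate curve
#'
#' Observed vs random event rate across significance thresholds, p-axis
#' log-scaled.
#'
#' @param object An [compute_event_rates()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot event_rate_curve
#' @export
autoplot.event_rate_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[c("threshold", "random_rate", "observed_rate")],
    c("random_rate", "observed_rate"),
    names_to = "series", values_to = "rate"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$threshold, y = .data$rate,
    colour = .data$series
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "p-value threshold", y = "event rate", colour = NULL,
      title = "Observed vs random X3 event rate"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an out-of-bag ROC curve
#'
#' @param object An [evaluate_oob()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot oob_eval
#' @export
autoplot.oob_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::annotate("point",
      x = 1 - object$specificity, y = object$sensitivity,
      colour = "red"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("Out-of-bag ROC (AUC = %.2f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot top gene importances
#'
#' @param importance Tibble from [mda_importance()].
#' @param top_k How many genes to show (default 25).
#' @return A ggplot.
#' @export
plot_importance <- function(importance, top_k = 25) {
  df <- filter(importance, .data$rank <= top_k)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$mda,
    y = stats::reorder(.data$gene_id, .data$mda)
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "mean decrease in accuracy", y = NULL,
      title = sprintf("Top %d genes by permutation importance", nrow(df))
    ) +
    ggplot2::theme_minimal()
}

#' Plot grade profiles
#'
#' Mean expression per (class, grade) cell for the selected genes and the
#' random baseline panel.
#'
#' @param object A [grade_profiles()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot grade_profiles
#' @export
autoplot.grade_profiles <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(cell = paste(.data$class, .data$grade, sep = "\n"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cell, y = .data$mean_expression,
    group = .data$gene_id, colour = .data$gene_id
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_expression - .data$sem,
        ymax = .data$mean_expression + .data$sem
      ),
      width = 0.15
    ) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(
      x = "class / grade", y = "mean expression (+/- SEM)",
      colour = NULL, title = "Mean expression by tumour class and grade"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a triplet across switch-gene bins
#'
#' X1 vs X2 faceted by the X3 bin, visualising the sign flip of the pair
#' correlation along the switch gene's expression.
#'
#' @param x Expression tibble or matrix.
#' @param x1_id,x2_id,x3_id Gene identifiers of the triplet.
#' @param bins Number of X3 bins (default 3).
#' @return A ggplot.
#' @export
plot_triplet_scatter <- function(x, x1_id, x2_id, x3_id, bins = 3) {
  m <- as_expr_matrix(x)
  x3 <- m[x3_id, ]
  grp <- bin_assign(x3, bins)
  df <- tibble(
    x1 = m[x1_id, ], x2 = m[x2_id, ],
    bin = factor(grp, labels = sprintf("%s bin %d", x3_id, seq_len(bins)))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x1, y = .data$x2)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~bin) +
    ggplot2::labs(x = x1_id, y = x2_id) +
    ggplot2::theme_minimal()
}

#' Plot a gene network
#'
#' Fruchterman-Reingold layout of the pruned MI network; highlighted genes
#' (e.g. switch genes) are coloured.
#'
#' @param object A `gene_network`.
#' @param highlight Character vector of gene ids to emphasise.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gene_network
#' @export
autoplot.gene_network <- function(object, highlight = character(), ...) {
  g <- network_igraph(object)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble(
    gene_id = igraph::V(g)$name, x = lay[, 1], y = lay[, 2],
    highlighted = igraph::V(g)$name %in% highlight
  )
  seg <- object$edges %>%
    left_join(nodes[c("gene_id", "x", "y")], by = c("gene_a" = "gene_id")) %>%
    rename(xa = "x", ya = "y") %>%
    left_join(nodes[c("gene_id", "x", "y")], by = c("gene_b" = "gene_id")) %>%
    rename(xb = "x", yb = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb),
      colour = "grey70"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$highlighted),
      size = 2
    ) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue", `TRUE` = "red")) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_void()
}
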