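#' Plot the forward-selection F-score trace of a classifier
#'
#' @param object A `kcml_classifier`.
#' @param ... Unused.
#' @return A ggplot: CV F-score against accepted-feature count.
#' @export
autoplot.kcml_classifier <- function(object, ...) {
  tr <- tidy(object)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$cv_fscore)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "accepted features", y = "mean CV F-score",
                  title = object$term) +
    ggplot2::theme_minimal()
}

#' Plot per-term metrics of a fit
#'
#' @param object A `kcml_fit`.
#' @param ... Unused.
#' @return A ggplot comparing test recall, train recall, FPR and AUROC per
#'   term, coloured by classifiability.
#' @export
autoplot.kcml_fit <- function(object, ...) {
  g <- glance(object)
  long <- tidyr::pivot_longer(
    g[, c("term", "classifiable", "test_recall", "train_recall",
          "false_positive_rate", "auroc")],
    cols = c("test_recall", "train_recall", "false_positive_rate", "auroc"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$term, y = .data$value,
                                     fill = .data$classifiable)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a term-overlap network
#'
#' @param net A `kcml_term_network`.
#' @param seed Layout seed.
#' @return A ggplot of the Fruchterman-Reingold layout; edge width encodes
#'   overlap, line type the edge origin (threshold vs attachment).
#' @export
plot_term_network <- function(net, seed = 1L) {
  set.seed(seed)
  # zero-weight attachment edges break weighted layouts
  lay <- igraph::layout_with_fr(net$graph,
                                weights = pmax(igraph::E(net$graph)$weight,
                                               1e-3))
  nodes <- tibble(term = igraph::V(net$graph)$name,
                  x = lay[, 1], y = lay[, 2])
  ed <- net$edges |>
    left_join(nodes, by = c(term_a = "term")) |>
    rename(x_a = "x", y_a = "y") |>
    left_join(nodes, by = c(term_b = "term")) |>
    rename(x_b = "x", y_b = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x_a, y = .data$y_a, xend = .data$x_b,
                   yend = .data$y_b, linewidth = .data$weight,
                   linetype = .data$origin),
      colour = "grey50") +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$term),
                       vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::theme_void()
}

#' Plot the signed feature-category summary
#'
#' @param summary Output of [feature_category_summary()].
#' @return A ggplot tile map: terms x categories, fill = scaled signed count
#'   (positive: above control; negative: below control).
#' @export
plot_feature_categories <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$category, y = .data$term,
                                        fill = .data$scaled)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a subphenotypic embedding
#'
#' @param emb Output of [subphenotypic_embedding()].
#' @return A ggplot of the 2-D coordinates coloured by predicted label.
#' @export
plot_subphenotypic_space <- function(emb) {
  ggplot2::ggplot(emb$coords, ggplot2::aes(.data$dim1, .data$dim2,
                                           colour = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::theme_minimal() +
    ggplot2::labs(colour = "predicted")
}
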