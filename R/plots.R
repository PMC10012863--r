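# ggplot2 presentation of results.

#' Plot an ROC curve
#'
#' @param object an `rt_roc` from [roc_curve()].
#' @param ... unused.
#' @return A ggplot: sensitivity against 1 - specificity with the chance
#'   diagonal.
#' @method autoplot rt_roc
#' @export
autoplot.rt_roc <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC (AUC = %.3f, %d+/%d-)",
                                  object$auc, object$n_pos, object$n_neg)) +
    ggplot2::theme_minimal()
}

#' Plot per-variable AUCs of an experiment
#'
#' @param object an `rt_experiment`.
#' @param ... unused.
#' @return A ggplot bar chart of per-variable AUC, faceted by test clinic,
#'   coloured by strategy; the pooled overall AUC is drawn as a dashed line.
#' @method autoplot rt_experiment
#' @export
autoplot.rt_experiment <- function(object, ...) {
  res <- object$results
  pv <- dplyr::filter(res, .data$variable != "overall", !is.na(.data$auc))
  ov <- dplyr::filter(res, .data$variable == "overall")
  ggplot2::ggplot(pv, ggplot2::aes(x = .data$auc,
                                   y = stats::reorder(.data$variable, .data$auc),
                                   fill = .data$strategy)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_vline(data = ov,
                        ggplot2::aes(xintercept = .data$auc,
                                     colour = .data$strategy),
                        linetype = "dashed", show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$test_clinic)) +
    ggplot2::labs(x = "AUC", y = NULL,
                  title = paste("Per-variable error detection AUC —",
                                object$config$setup)) +
    ggplot2::theme_minimal()
}

#' Plot the network structure
#'
#' @param network an [rt_network()].
#' @param seed layout seed.
#' @return A ggplot of the DAG (Sugiyama-style layered layout), nodes
#'   coloured by variable category.
#' @export
plot_structure <- function(network, seed = 42L) {
  g <- igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                     vertices = network$nodes)
  lay <- with_seed(seed, igraph::layout_with_sugiyama(g)$layout)
  nodes <- tibble::tibble(name = network$nodes,
                          x = lay[, 1], y = lay[, 2],
                          category = network$schema$category[
                            match(network$nodes, network$schema$variable)])
  ed <- dplyr::mutate(network$edges,
                      x = nodes$x[match(.data$from, nodes$name)],
                      y = nodes$y[match(.data$from, nodes$name)],
                      xend = nodes$x[match(.data$to, nodes$name)],
                      yend = nodes$y[match(.data$to, nodes$name)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$name, fill = .data$category),
                        size = 2.6, alpha = 0.9) +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "category")
}
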