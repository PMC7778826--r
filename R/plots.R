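#' @export
autoplot.psn_roc <- function(object, ...) {
  ggplot(object, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_step() +
    coord_equal() +
    labs(x = "False-positive rate", y = "True-positive rate",
         title = "ROC curve") +
    theme_minimal()
}

#' @export
autoplot.psn_pr <- function(object, ...) {
  ggplot(object, aes(x = .data$recall, y = .data$precision)) +
    geom_step(direction = "vh") +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "Recall", y = "Precision", title = "Precision-recall curve") +
    theme_minimal()
}

#' @export
autoplot.mda_ranking <- function(object, top = 20, ...) {
  d <- utils::head(object$ranking, top)
  ggplot(d, aes(x = stats::reorder(.data$feature, .data$mda),
                y = .data$mda)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(aes(ymin = .data$mda - .data$sd,
                      ymax = .data$mda + .data$sd), width = 0.3) +
    coord_flip() +
    labs(x = NULL, y = "Mean decrease in accuracy (percentage points)",
         title = "Leave-one-feature-out importance") +
    theme_minimal()
}

#' @export
autoplot.atest_result <- function(object, ...) {
  ggplot(object$gamma_k, aes(x = .data$K, y = .data$gamma)) +
    geom_line() + geom_point() +
    geom_hline(yintercept = object$gamma_hat, linetype = "dashed") +
    labs(x = "K (balanced folds)", y = expression(Gamma[K]~"(%)"),
         title = "A-Test structural risk") +
    theme_minimal()
}

#' @export
autoplot.psn_pdp <- function(object, ...) {
  ggplot(object, aes(x = .data$value, y = .data$score)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = attr(object, "feature"), y = "Mean model score",
         title = "Partial dependence") +
    theme_minimal()
}

#' Plot a similarity network
#'
#' Force-directed sketch of a `psn_network`, edge opacity proportional to
#' similarity (1 - weight), useful for eyeballing threshold effects.
#'
#' @param network A `psn_network`.
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_network <- function(network, seed = 1L) {
  set.seed(seed)
  lay <- igraph::layout_with_fr(network$graph)
  nodes <- tibble(name = network$nodes, x = lay[, 1], y = lay[, 2])
  e <- network_edges(network)
  e <- e %>%
    left_join(nodes, by = c(from = "name")) %>%
    rename(x1 = "x", y1 = "y") %>%
    left_join(nodes, by = c(to = "name")) %>%
    rename(x2 = "x", y2 = "y")
  ggplot() +
    geom_segment(data = e, aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                               yend = .data$y2,
                               alpha = 1 - .data$weight),
                 colour = "grey40", show.legend = FALSE) +
    geom_point(data = nodes, aes(x = .data$x, y = .data$y),
               colour = "steelblue") +
    theme_void()
}
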