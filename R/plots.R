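# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Boxplot of a trait by cluster with Duncan letters
#'
#' @param object A [duncan_mrt()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dmrt
#' @export
autoplot.dmrt <- function(object, ...) {
  d <- object$data
  g <- object$groups
  d$cluster <- factor(d$cluster, levels = g$cluster)
  lab <- g
  lab$y <- max(d$value) + 0.05 * diff(range(d$value)) + 1e-9
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cluster, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(x = .data$cluster, y = .data$y,
                                    label = .data$letters)) +
    ggplot2::labs(x = "Cluster", y = "Trait value",
                  subtitle = sprintf("ANOVA p = %.3g", object$anova$p_value)) +
    ggplot2::theme_minimal()
}

#' Mean r-squared against physical distance
#'
#' @param object An [ld_decay()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ld_decay
#' @export
autoplot.ld_decay <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid / 1e3,
                                            y = .data$mean_r2)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Distance (kb)", y = expression(mean~r^2)) +
    ggplot2::theme_minimal()
  thr <- attr(object, "r2_threshold")
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = 2)
  }
  p
}

#' Cumulative pair coverage of a core marker set
#'
#' @param object A `core_set` from [greedy_min_set()] or [nested_sets()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot core_set
#' @export
autoplot.core_set <- function(object, ...) {
  d <- tibble::tibble(rank = object$rank,
                      covered = cumsum(object$pairs_new))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$covered)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = attr(object, "n_pairs"), linetype = 2) +
    ggplot2::labs(x = "Markers in set", y = "Variety pairs separated") +
    ggplot2::theme_minimal()
}

#' PCA score plot of the varieties
#'
#' @param pca A [pca_variance()] result.
#' @param clusters Optional assignment tibble (variety, cluster) to colour
#'   points.
#' @return A ggplot of the first two components.
#' @export
plot_pca <- function(pca, clusters = NULL) {
  sc <- attr(pca, "scores")
  d <- tibble::tibble(variety = rownames(sc), PC1 = sc[, 1], PC2 = sc[, 2])
  if (!is.null(clusters)) {
    d <- dplyr::left_join(d, clusters, by = "variety")
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                         colour = factor(.data$cluster)))
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * pca$variance_fraction[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * pca$variance_fraction[2]),
      colour = "Cluster") +
    ggplot2::theme_minimal()
}
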