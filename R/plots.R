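#' Plot an accuracy sweep across orderings and influence coefficients
#'
#' Accuracy as a function of the horizontal influence coefficient, one line
#' per ordering method — the standard benchmark figure for comparing the
#' ant-colony ordering with ranking, clustering and random baselines.
#'
#' @param object An `ixp_sweep` tibble from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ixp_sweep
#' @export
autoplot.ixp_sweep <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$r, y = .data$accuracy,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "horizontal influence coefficient r",
                  y = "test accuracy", colour = "ordering") +
    ggplot2::theme_minimal()
}

#' Plot integrated expression profiles
#'
#' Group-average integrated profiles along the ordered gene axis when labels
#' are present, per-sample curves otherwise.
#'
#' @param object An [ixp_features] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ixp_features
#' @export
autoplot.ixp_features <- function(object, ...) {
  if (!is.null(object$labels)) {
    df <- group_average_profile(object)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$value,
                                          colour = .data$class)) +
      ggplot2::geom_line()
  } else {
    df <- tidy(object)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$value,
                                          group = .data$sample)) +
      ggplot2::geom_line(alpha = 0.4)
  }
  p + ggplot2::labs(x = "ordering position", y = "integrated expression") +
    ggplot2::theme_minimal()
}

#' Heatmap of a reordered adjacency matrix
#'
#' Rows and columns of the interaction matrix permuted into ordering
#' positions; block and band patterns indicate that interacting genes sit at
#' nearby positions.
#'
#' @param net A [ppi_network].
#' @param ord A node ordering covering the network's genes.
#' @return A ggplot object.
#' @export
plot_reordered_adjacency <- function(net, ord) {
  check_ordering_matches(net, ord)
  pos <- stats::setNames(ord$position, ord$gene)
  df <- tibble::tibble(i = pos[net$edges$gene_a], j = pos[net$edges$gene_b])
  df <- dplyr::bind_rows(df, tibble::tibble(i = df$j, j = df$i))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_tile(fill = "grey20") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "position", y = "position") +
    ggplot2::theme_minimal()
}
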