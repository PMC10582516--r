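# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Log-log degree-distribution plot with the fitted power law
#'
#' Empirical complementary CDF of the degree sample on log-log axes, with
#' the fitted discrete power-law tail overlaid from `xmin` upwards.
#'
#' @param object A [fit_powerlaw()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  ks <- sort(unique(object$degrees))
  n <- length(object$degrees)
  ccdf <- vapply(ks, function(k) sum(object$degrees >= k) / n, numeric(1L))
  emp <- tibble::tibble(k = ks, ccdf = ccdf)
  z0 <- hurwitz_zeta(object$alpha, object$xmin)
  scale_at <- sum(object$degrees >= object$xmin) / n
  fit_k <- ks[ks >= object$xmin]
  fit <- tibble::tibble(
    k = fit_k,
    ccdf = scale_at * vapply(fit_k, function(k) {
      hurwitz_zeta(object$alpha, k) / z0
    }, numeric(1L))
  )
  ggplot2::ggplot(emp, ggplot2::aes(x = .data$k, y = .data$ccdf)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = fit, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "P(K >= k)",
                  title = sprintf("Discrete power law: alpha = %.2f, xmin = %d",
                                  object$alpha, object$xmin)) +
    ggplot2::theme_minimal()
}

#' Entropy-rate perturbation plot
#'
#' Perturbed global entropy rate against log degree, one point per vertex
#' and direction (over-/under-expression). Scale-free-like networks show
#' the characteristic bi-modal, bi-phasic pattern: over-expression lowers
#' SR most at hubs while under-expression raises it.
#'
#' @param object A [perturb_entropy()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.entropy_perturbation <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("SR_over", "SR_under"),
                              names_to = "direction", values_to = "SR")
  long$direction <- ifelse(long$direction == "SR_over",
                           "over-expression", "under-expression")
  ggplot2::ggplot(long, ggplot2::aes(x = log(.data$degree), y = .data$SR,
                                     colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c("over-expression" = "red",
                                            "under-expression" = "darkgreen")) +
    ggplot2::labs(x = "log degree", y = "entropy rate SR (nats)") +
    ggplot2::theme_minimal()
}

#' Consensus-matrix heatmap
#'
#' @param object A [consensus_matrix()].
#' @param order_by Optional `network_clustering` used to order vertices by
#'   community.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.consensus_matrix <- function(object, order_by = NULL, ...) {
  ord <- seq_along(object$vertices)
  if (!is.null(order_by)) {
    ord <- order(order_by$membership[object$vertices])
  }
  ids <- object$vertices[ord]
  long <- tidy.consensus_matrix(object)
  long$vertex_a <- factor(long$vertex_a, levels = ids)
  long$vertex_b <- factor(long$vertex_b, levels = ids)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$vertex_a, y = .data$vertex_b,
                                     fill = .data$consensus)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Influence plot: bridgeness against a normalised centrality
#'
#' Scatter of bridgeness versus the paired centrality with the quadrant
#' thresholds drawn; vertices in the upper-left act as global bridges,
#' lower-right as local hubs.
#'
#' @param it An [influence_table()] result.
#' @param thresholds Length-2 numeric thresholds to draw (default 0.5/0.5).
#' @return A ggplot object.
#' @export
plot_influence <- function(it, thresholds = c(0.5, 0.5)) {
  ggplot2::ggplot(it, ggplot2::aes(x = .data$centrality, y = .data$bridgeness,
                                   colour = .data$quadrant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = thresholds[1L], linetype = "dashed") +
    ggplot2::geom_vline(xintercept = thresholds[2L], linetype = "dashed") +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "normalised centrality", y = "bridgeness") +
    ggplot2::theme_minimal()
}

#' Plot a community-aware layout
#'
#' @param net The network the layout was computed for.
#' @param layout A [cluster_layout()] tibble.
#' @return A ggplot object with edges and community-coloured vertices.
#' @export
plot_cluster_layout <- function(net, layout) {
  el <- igraph::as_edgelist(net, names = TRUE)
  pos <- stats::setNames(seq_len(nrow(layout)), layout$vertex_id)
  seg <- tibble::tibble(
    x = layout$x[pos[el[, 1L]]], y = layout$y[pos[el[, 1L]]],
    xend = layout$x[pos[el[, 2L]]], yend = layout$y[pos[el[, 2L]]]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70", linewidth = 0.2) +
    ggplot2::geom_point(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = factor(.data$community))) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_void()
}
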