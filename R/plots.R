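# ggplot2 displays for the package's result objects.

#' @describeIn fit_sudden_expansion `autoplot()`: observed mismatch
#'   distribution (bars) with the fitted sudden-expansion curve (line).
#' @param object The fitted object.
#' @export
autoplot.mismatch_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$differences)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed),
                      fill = "grey70", width = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected),
                        colour = "firebrick", size = 1.4) +
    ggplot2::labs(
      x = "Pairwise differences", y = "Frequency",
      title = "Mismatch distribution",
      subtitle = sprintf("sudden expansion: tau = %.2f, theta0 = %.2f, theta1 = %.2f",
                         object$tau, object$theta0, object$theta1)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn wu_kabat_profile `autoplot()`: per-codon variability with
#'   the 2 x mean threshold; conserved fragments underlined.
#' @param object The profile object.
#' @param ... Unused.
#' @export
autoplot.wu_kabat <- function(object, ...) {
  df <- object$profile
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$codon, y = .data$W)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.8) +
    ggplot2::geom_hline(yintercept = 2 * object$mean_W,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Codon", y = "Wu-Kabat variability (W)",
                  title = "Wu-Kabat variability profile",
                  subtitle = sprintf("mean W = %.2f; dashed line at 2 x mean",
                                     object$mean_W)) +
    ggplot2::theme_minimal()
  if (nrow(object$conserved_runs) > 0) {
    p <- p + ggplot2::geom_segment(
      data = object$conserved_runs,
      ggplot2::aes(x = .data$start - 0.4, xend = .data$end + 0.4,
                   y = -0.05 * max(df$W, na.rm = TRUE),
                   yend = -0.05 * max(df$W, na.rm = TRUE)),
      inherit.aes = FALSE, linewidth = 1.6, colour = "purple"
    )
  }
  p
}

#' @describeIn minimum_spanning_network `autoplot()`: network drawn on a
#'   classical multidimensional scaling of Hamming distances; solid
#'   segments are spanning edges, dashed ones co-minimal alternatives;
#'   point area tracks haplotype frequency.
#' @param object The network object.
#' @param ... Unused.
#' @export
autoplot.haplotype_network <- function(object, ...) {
  nodes <- object$nodes
  edges <- object$edges
  if (nrow(nodes) > 2) {
    d <- matrix(0, nrow(nodes), nrow(nodes),
                dimnames = list(nodes$id, nodes$id))
    for (r in seq_len(nrow(edges))) {
      d[edges$from[r], edges$to[r]] <- edges$distance[r]
      d[edges$to[r], edges$from[r]] <- edges$distance[r]
    }
    # graph distances along missing entries default to max; crude but
    # adequate for display
    d[d == 0 & row(d) != col(d)] <- max(edges$distance) * 1.5
    xy <- stats::cmdscale(stats::as.dist(d), k = 2)
  } else {
    xy <- cbind(seq_len(nrow(nodes)), 0)
  }
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  if (nrow(edges) > 0) {
    edges$x <- nodes$x[match(edges$from, nodes$id)]
    edges$y <- nodes$y[match(edges$from, nodes$id)]
    edges$xend <- nodes$x[match(edges$to, nodes$id)]
    edges$yend <- nodes$y[match(edges$to, nodes$id)]
  }
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = !.data$in_mst),
      colour = "grey50", show.legend = FALSE
    )
  }
  p +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$frequency),
      colour = "steelblue", alpha = 0.8
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$id),
      vjust = -1.2, size = 3
    ) +
    ggplot2::labs(title = "Minimum spanning haplotype network",
                  size = "Frequency") +
    ggplot2::theme_void()
}
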