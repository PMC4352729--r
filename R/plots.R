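#' Plot Kaplan-Meier curves
#'
#' Step-function survival curves, one per group, with censoring ticks.
#'
#' @param object A `km_curve` from [kaplan_meier()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  tb <- tibble::as_tibble(object)
  has_group <- "group" %in% names(tb)
  if (!has_group) tb$group <- "all"
  # prepend S(0) = 1 so the step starts at the origin
  origin <- dplyr::distinct(tb, .data$group)
  origin$time <- 0
  origin$survival <- 1
  tb2 <- dplyr::bind_rows(origin, tb[, c("group", "time", "survival")])
  p <- ggplot2::ggplot(tb2, ggplot2::aes(.data$time, .data$survival,
                                         colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
  cens <- tb[tb$n_censor > 0, ]
  if (nrow(cens)) {
    p <- p + ggplot2::geom_point(data = cens, shape = 3, show.legend = FALSE)
  }
  if (!has_group) p <- p + ggplot2::guides(colour = "none")
  p
}

#' Plot a typed multi-omics network
#'
#' Nodes on a circle, coloured by molecular layer; undirected (reversible)
#' edges are drawn dashed without arrowheads.
#'
#' @param object An `omics_network`.
#' @param label Draw node labels.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot omics_network
#' @export
autoplot.omics_network <- function(object, label = TRUE, ...) {
  nodes <- object$nodes
  n <- nrow(nodes)
  if (n == 0) stop("cannot plot an empty network", call. = FALSE)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  pos <- tibble::tibble(node = nodes$node, layer = nodes$layer,
                        x = cos(theta), y = sin(theta))
  ed <- dplyr::left_join(
    dplyr::left_join(object$edges, pos[, c("node", "x", "y")],
                     by = c(from = "node")),
    dplyr::rename(pos[, c("node", "x", "y")], xend = "x", yend = "y"),
    by = c(to = "node"))
  p <- ggplot2::ggplot()
  if (nrow(ed)) {
    dirseg <- ed[ed$directed, ]
    undseg <- ed[!ed$directed, ]
    if (nrow(dirseg)) {
      p <- p + ggplot2::geom_segment(
        data = dirseg,
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
        arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"), type = "closed"),
        colour = "grey40", linewidth = 0.3)
    }
    if (nrow(undseg)) {
      p <- p + ggplot2::geom_segment(
        data = undseg,
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
        linetype = "dashed", colour = "grey40", linewidth = 0.3)
    }
  }
  p <- p + ggplot2::geom_point(
    data = pos, ggplot2::aes(.data$x, .data$y, colour = .data$layer), size = 3) +
    ggplot2::coord_equal() + ggplot2::theme_void() +
    ggplot2::labs(colour = "layer")
  if (label) {
    p <- p + ggplot2::geom_text(
      data = pos, ggplot2::aes(.data$x * 1.08, .data$y * 1.08, label = .data$node),
      size = 2.5)
  }
  p
}

#' @method tidy omics_network
#' @export
tidy.omics_network <- function(x, ...) {
  dplyr::mutate(x$edges,
                from_layer = sub(":.*$", "", .data$from),
                to_layer = sub(":.*$", "", .data$to))
}

#' @method glance omics_network
#' @export
glance.omics_network <- function(x, ...) {
  st <- network_stats(x)
  tibble::tibble(n_nodes = st$n_nodes,
                 n_mrna = st$nodes_by_layer[["mrna"]],
                 n_mirna = st$nodes_by_layer[["mirna"]],
                 n_methylation = st$nodes_by_layer[["methylation"]],
                 n_cnv = st$nodes_by_layer[["cnv"]],
                 n_edges = st$n_edges, n_undirected = st$n_undirected,
                 score = if (is.null(x$score)) NA_real_ else x$score)
}
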