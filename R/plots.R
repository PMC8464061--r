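#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Dendrogram segment coordinates: leaves at integer x positions in
# left-to-right tree order, internal nodes centered over their children.
taxonomy_segments <- function(tax) {
  nodes <- tax$nodes
  leaf_x <- new.env()
  counter <- 0
  xpos <- setNames(rep(NA_real_, nrow(nodes)), nodes$node_id)
  assign_x <- function(id) {
    i <- match(id, nodes$node_id)
    if (nodes$is_leaf[i]) {
      counter <<- counter + 1
      xpos[id] <<- counter
    } else {
      kids <- nodes$children[[i]]
      assign_x(kids[1L])
      assign_x(kids[2L])
      xpos[id] <<- mean(xpos[kids])
    }
  }
  assign_x(nodes$node_id[is.na(nodes$parent)])
  segs <- list()
  for (i in seq_len(nrow(nodes))) {
    if (nodes$is_leaf[i]) next
    kids <- nodes$children[[i]]
    hk <- nodes$height[match(kids, nodes$node_id)]
    segs[[length(segs) + 1L]] <- tibble(
      x = c(xpos[kids], min(xpos[kids])),
      xend = c(xpos[kids], max(xpos[kids])),
      y = c(hk, rep(nodes$height[i], 1L)),
      yend = rep(nodes$height[i], 3L)
    )
  }
  list(segments = dplyr::bind_rows(segs), x = xpos, nodes = nodes)
}

#' Plot a taxonomy as a dendrogram
#'
#' Branch heights are the stability-derived node heights; internal nodes are
#' annotated with their partition stability.
#'
#' @param object A `k2_taxonomy` with heights computed.
#' @param label_ps Annotate internal nodes with their stability score.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot k2_taxonomy
#' @export
autoplot.k2_taxonomy <- function(object, label_ps = TRUE, ...) {
  sc <- taxonomy_segments(object)
  nodes <- sc$nodes
  leaves <- nodes[nodes$is_leaf, ]
  leaf_lab <- vapply(
    seq_len(nrow(leaves)),
    function(i) {
      if (leaves$n_items[i] == 1L) {
        leaves$items[[i]]
      } else {
        sprintf("%s (%d)", leaves$node_id[i], leaves$n_items[i])
      }
    },
    character(1)
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = sc$segments,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend)
    ) +
    ggplot2::annotate(
      "text",
      x = sc$x[leaves$node_id], y = leaves$height,
      label = leaf_lab, angle = 90, hjust = 1.1, size = 3
    ) +
    ggplot2::labs(x = NULL, y = "node height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      panel.grid.major.x = ggplot2::element_blank(),
      panel.grid.minor.x = ggplot2::element_blank()
    )
  if (label_ps) {
    internal <- nodes[!nodes$is_leaf, ]
    p <- p + ggplot2::annotate(
      "label",
      x = sc$x[internal$node_id], y = internal$height,
      label = sprintf("%.2f", internal$ps), size = 2.7
    )
  }
  p
}

#' Plot benchmark results
#'
#' Mean Baker's gamma against noise level, one line per method, faceted by
#' the number of terminal clusters.
#'
#' @param object A `k2_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot k2_benchmark
#' @export
autoplot.k2_benchmark <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$summary,
    cols = c("mean_k2tax", "mean_ward"),
    names_to = "method", values_to = "mean_gamma",
    names_prefix = "mean_"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$noise_sd, y = .data$mean_gamma,
      colour = .data$method
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$n_terminal_clusters),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(
      x = "noise standard deviation",
      y = "mean Baker's gamma vs generating tree", colour = NULL
    ) +
    ggplot2::theme_minimal()
}
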