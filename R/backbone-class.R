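# Tibble-backed result containers.
#
# backbone_result: one row per tested dyad with the observed weight and the
#   upper/lower-tail p-values under the model's null (the alpha = NULL object).
# backbone: one row per retained edge with its sign, plus provenance
#   (model, alpha, mtc, reduction statistics) in attributes.

original_stats <- function(A) {
  list(
    n_nodes = nrow(A),
    n_edges = sum(A[upper.tri(A)] > 0),
    n_connected = sum(rowSums(A > 0) > 0)
  )
}

new_backbone_result <- function(edges, nodes, model, params, orig,
                                tested = c("positive", "all"),
                                network_desc = NULL) {
  tested <- match.arg(tested)
  out <- tibble::new_tibble(
    edges,
    nodes = nodes,
    model = model,
    params = params,
    orig_stats = original_stats(orig),
    tested = tested,
    network_desc = network_desc,
    class = "backbone_result"
  )
  out
}

new_backbone <- function(edges, nodes, model, params, orig_stats,
                         alpha = NULL, mtc = "none", signed = FALSE,
                         network_desc = NULL, citations = character()) {
  deg <- table(factor(c(edges$from, edges$to), levels = nodes))
  n_connected_bb <- sum(deg > 0)
  stats <- list(
    n_nodes = length(nodes),
    n_edges_original = orig_stats$n_edges,
    n_edges = nrow(edges),
    n_connected_original = orig_stats$n_connected,
    n_connected = n_connected_bb,
    edge_reduction_pct =
      100 * (1 - nrow(edges) / max(orig_stats$n_edges, 1)),
    node_reduction_pct =
      100 * (1 - n_connected_bb / max(orig_stats$n_connected, 1))
  )
  tibble::new_tibble(
    edges,
    nodes = nodes,
    model = model,
    params = params,
    alpha = alpha,
    mtc = mtc,
    signed = signed,
    stats = stats,
    network_desc = network_desc,
    citations = citations,
    class = "backbone"
  )
}

fmt_pct <- function(x) {
  s <- sprintf("%.1f", x)
  s <- sub("\\.0$", "", s)
  paste0(s, "%")
}

#' @export
print.backbone <- function(x, ...) {
  st <- attr(x, "stats")
  cat(sprintf("# Backbone: %s%s%s\n",
              attr(x, "model"),
              if (!is.null(attr(x, "alpha")))
                sprintf(" (alpha = %g, mtc = %s)", attr(x, "alpha"), attr(x, "mtc"))
              else "",
              if (isTRUE(attr(x, "signed"))) " [signed]" else ""))
  cat(sprintf("# %d nodes; %d of %d edges kept (%s reduction); %d of %d connected nodes (%s reduction)\n",
              st$n_nodes, st$n_edges, st$n_edges_original,
              fmt_pct(st$edge_reduction_pct),
              st$n_connected, st$n_connected_original,
              fmt_pct(st$node_reduction_pct)))
  y <- x
  class(y) <- c("tbl_df", "tbl", "data.frame")
  print(y, ...)
  invisible(x)
}

#' @export
print.backbone_result <- function(x, ...) {
  cat(sprintf("# Edgewise p-values: %s model, %d tested dyads (%s)\n",
              attr(x, "model"), nrow(x),
              if (attr(x, "tested") == "all") "all dyads" else "positive-weight dyads"))
  y <- x
  class(y) <- c("tbl_df", "tbl", "data.frame")
  print(y, ...)
  invisible(x)
}

#' Tidy an extracted backbone or p-value object
#'
#' @param x A `backbone` or `backbone_result` object.
#' @param ... Unused.
#' @return A plain tibble: per-edge rows (`from`, `to`, `sign`) for a
#'   backbone; per-dyad rows (`from`, `to`, `weight`, `p_upper`, `p_lower`)
#'   for a p-value object.
#' @method tidy backbone
#' @export
tidy.backbone <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @rdname tidy.backbone
#' @method tidy backbone_result
#' @export
tidy.backbone_result <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' One-row summary of a backbone
#'
#' @param x A `backbone` object.
#' @param ... Unused.
#' @return A one-row tibble: model, alpha, mtc, signed flag, node and edge
#'   counts, and the edge / connected-node reduction percentages.
#' @method glance backbone
#' @export
glance.backbone <- function(x, ...) {
  st <- attr(x, "stats")
  tibble::tibble(
    model = attr(x, "model"),
    alpha = attr(x, "alpha") %||% NA_real_,
    mtc = attr(x, "mtc"),
    signed = attr(x, "signed"),
    n_nodes = st$n_nodes,
    n_edges_original = st$n_edges_original,
    n_edges = st$n_edges,
    edge_reduction_pct = st$edge_reduction_pct,
    node_reduction_pct = st$node_reduction_pct
  )
}

#' Plot a backbone
#'
#' Draws the backbone with a force-directed (Fruchterman-Reingold) layout.
#' Positive edges are solid; negative edges (signed backbones) are drawn
#' dashed red.
#'
#' @param object A `backbone` object.
#' @param seed Integer seed for the layout (layouts are stochastic).
#' @param labels Logical; draw node labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot backbone
#' @export
autoplot.backbone <- function(object, seed = 1, labels = TRUE, ...) {
  nodes <- attr(object, "nodes")
  g <- igraph::graph_from_data_frame(
    as.data.frame(object)[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  xy <- with_seed_if(seed, igraph::layout_with_fr(g))
  node_df <- tibble::tibble(name = nodes, x = xy[, 1], y = xy[, 2])
  edge_df <- tibble::as_tibble(as.data.frame(object))
  if (!"sign" %in% names(edge_df)) edge_df$sign <- 1
  edge_df$xa <- node_df$x[match(edge_df$from, node_df$name)]
  edge_df$ya <- node_df$y[match(edge_df$from, node_df$name)]
  edge_df$xb <- node_df$x[match(edge_df$to, node_df$name)]
  edge_df$yb <- node_df$y[match(edge_df$to, node_df$name)]
  edge_df$tie <- factor(ifelse(edge_df$sign > 0, "positive", "negative"),
                        levels = c("positive", "negative"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edge_df,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb,
                   colour = .data$tie, linetype = .data$tie),
      linewidth = 0.4
    ) +
    ggplot2::geom_point(data = node_df,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 2) +
    ggplot2::scale_colour_manual(values = c(positive = "grey30", negative = "firebrick"),
                                 drop = FALSE) +
    ggplot2::scale_linetype_manual(values = c(positive = "solid", negative = "dashed"),
                                   drop = FALSE) +
    ggplot2::labs(title = sprintf("%s backbone", attr(object, "model")),
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_void()
  if (labels) {
    p <- p + ggplot2::geom_text(
      data = node_df,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      vjust = -0.8, size = 3
    )
  }
  p
}

#' @export
plot.backbone <- function(x, ...) print(autoplot(x, ...))
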