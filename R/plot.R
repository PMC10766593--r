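# Structure-plot rendering. Every mode is a stacked bar chart (one bar
# per individual, segment heights = memberships, one color per global
# cluster index); modes sit in layers by K, and edges between adjacent
# layers are drawn darker the closer the alignment, labeled with the
# optimal dissimilarity. All quantities are taken from upstream results;
# nothing is aligned or scored here.

mode_palette <- function(n) {
  base <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442", "#0072B2",
            "#D55E00", "#CC79A7", "#999999", "#8DD3C7", "#BEBADA",
            "#FB8072", "#80B1D3", "#FDB462", "#B3DE69", "#FCCDE5",
            "#BC80BD", "#CCEBC5", "#FFED6F", "#1B9E77", "#7570B3")
  rep_len(base, n)
}

#' Draw the multipartite structure-plot figure
#'
#' @param layout a [compute_global_layout()] result.
#' @param graph the [build_across_k_graph()] result the layout came from.
#' @param labels optional character vector of individual labels (annotation
#'   only; drawn under the widest layer when provided).
#' @return a ggplot object.
#' @export
plot_mode_graph <- function(layout, graph, labels = NULL) {
  ks <- layout$k_values
  n_layer <- length(ks)
  panel_gap <- 0.35       # horizontal gap between mode panels, bar units
  layer_gap <- 0.8        # vertical gap between layers
  N <- nrow(as_matrix(consensus_matrix(graph$layers[[1L]][[1L]])))

  rects <- list()
  panel_center <- list()
  titles <- list()
  max_color <- 0L
  for (p in seq_len(n_layer)) {
    modes <- graph$layers[[p]]
    y0 <- (n_layer - p) * (1 + layer_gap)
    x0 <- 0
    for (m in seq_along(modes)) {
      mat <- as_matrix(consensus_matrix(modes[[m]], graph$consensus_method))
      K <- ncol(mat)
      slot <- layout$perms[[p]][[m]]
      cols <- layout$colors[[p]][[m]]
      max_color <- max(max_color, cols)
      draw_order <- order(slot)            # stack bottom-up in slot order
      cum <- rbind(0, apply(mat[, draw_order, drop = FALSE], 1L, cumsum))
      for (s in seq_len(K)) {
        rects[[length(rects) + 1L]] <- data.frame(
          xmin = x0 + seq_len(N) - 1L, xmax = x0 + seq_len(N),
          ymin = y0 + cum[s, ], ymax = y0 + cum[s + 1L, ],
          color_id = cols[draw_order[s]]
        )
      }
      panel_center[[paste(p, m)]] <- c(x = x0 + N / 2, top = y0 + 1, bottom = y0)
      titles[[length(titles) + 1L]] <- data.frame(
        x = x0 + N / 2, y = y0 + 1.12,
        label = sprintf("K%d-M%d (%d)", ks[p], m,
                        length(modes[[m]]$member_ids))
      )
      x0 <- x0 + N * (1 + panel_gap)
    }
  }
  rects <- do.call(rbind, rects)
  titles <- do.call(rbind, titles)

  segs <- NULL
  edge_labels <- NULL
  if (n_layer > 1L) {
    segs <- list(); edge_labels <- list()
    for (p in seq_len(n_layer - 1L)) {
      for (e in layout$edges[[p]]) {
        up <- panel_center[[paste(p, e$hi_mode)]]
        lo <- panel_center[[paste(p + 1L, e$lo_mode)]]
        mu <- min(max(e$weight, 0), 1)   # darkness clip, drawing only
        segs[[length(segs) + 1L]] <- data.frame(
          x = up["x"], y = up["bottom"], xend = lo["x"], yend = lo["top"],
          shade = grDevices::grey(0.88 * (1 - mu))
        )
        edge_labels[[length(edge_labels) + 1L]] <- data.frame(
          x = (up["x"] + lo["x"]) / 2, y = (up["bottom"] + lo["top"]) / 2,
          label = sprintf("%.3f", e$cost)
        )
      }
    }
    segs <- do.call(rbind, segs)
    edge_labels <- do.call(rbind, edge_labels)
  }

  pal <- mode_palette(max_color)
  g <- ggplot2::ggplot()
  if (!is.null(segs)) {
    g <- g +
      ggplot2::geom_segment(
        data = segs,
        ggplot2::aes(x = .data$x, y = .data$y,
                     xend = .data$xend, yend = .data$yend),
        color = segs$shade, linewidth = 0.8) +
      ggplot2::geom_label(
        data = edge_labels,
        ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
        size = 2.6, label.size = 0)
  }
  g +
    ggplot2::geom_rect(
      data = rects,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax,
                   fill = factor(.data$color_id))) +
    ggplot2::geom_text(
      data = titles,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      size = 3) +
    ggplot2::scale_fill_manual(values = pal, guide = "none") +
    ggplot2::theme_void()
}

#' Render the multipartite figure to a file
#'
#' @inheritParams plot_mode_graph
#' @param out_path output file path (extension ignored).
#' @param format `"png"`, `"svg"`, or `"pdf"`.
#' @param width,height,dpi figure parameters passed to [ggplot2::ggsave()].
#' @return the written file path.
#' @export
render_modes <- function(layout, graph, out_path, format = c("png", "svg", "pdf"),
                         width = 9, height = 6, dpi = 150) {
  format <- match.arg(format)
  out_path <- paste0(tools::file_path_sans_ext(out_path), ".", format)
  g <- plot_mode_graph(layout, graph)
  dev <- switch(format, png = grDevices::png, svg = grDevices::svg,
                pdf = grDevices::pdf)
  ggplot2::ggsave(out_path, g, device = dev, width = width, height = height,
                  dpi = dpi)
  out_path
}

#' Histograms of within-mode pairwise dissimilarities
#'
#' One panel per non-singleton mode of a replicate graph, showing the
#' distribution of optimal pairwise alignment dissimilarities among the
#' mode's members.
#'
#' @param graph a [build_replicate_graph()] result.
#' @param mode_set the [detect_modes()] result over the same graph.
#' @return a ggplot object, or `NULL` when every mode is a singleton.
#' @export
plot_mode_histograms <- function(graph, mode_set) {
  rows <- list()
  for (l in seq_along(mode_set$modes)) {
    members <- mode_set$modes[[l]]
    if (length(members) < 2L) next
    idx <- match(members, graph$node_ids)
    D <- graph$dissimilarities[idx, idx]
    rows[[length(rows) + 1L]] <- data.frame(
      mode = sprintf("K%d-M%d", mode_set$K, l),
      dissimilarity = D[upper.tri(D)]
    )
  }
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dissimilarity)) +
    ggplot2::geom_histogram(bins = 30, fill = "#56B4E9", color = "grey30") +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = "pairwise dissimilarity under optimal alignment",
                  y = "pairs") +
    ggplot2::theme_bw()
}
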