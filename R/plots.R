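# ggplot2 views of the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a PCoA ordination
#'
#' @param object An `ms_pcoa`.
#' @param ... Unused.
#' @return A ggplot; points coloured by ecosystem label when the
#'   coordinates carry group labels (queries are labelled `"query"`).
#' @export
autoplot.ms_pcoa <- function(object, ...) {
  df <- tidy(object)
  df$group <- attr(object, "groups") %||% "sample"
  if (!"Axis2" %in% names(df)) df$Axis2 <- 0
  ev <- attr(object, "eigenvalues")
  pct <- if (length(ev) >= 2L) round(100 * ev[1:2] / sum(ev), 1) else c(NA, NA)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis1, y = .data$Axis2,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = paste0("PCo1 (", pct[1], "%)"),
                  y = paste0("PCo2 (", pct[2], "%)"),
                  colour = "ecosystem") +
    ggplot2::theme_minimal()
}

#' Plot a UPGMA dendrogram
#'
#' @param object An `ms_dendro`.
#' @param ... Unused.
#' @return A ggplot drawing the merge tree with ultrametric heights.
#' @export
autoplot.ms_dendro <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$labels)
  xpos <- numeric(n)
  xpos[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge))
  node_y <- object$heights
  segs <- vector("list", nrow(hc$merge))
  pos <- function(v) if (v < 0) c(xpos[-v], 0) else c(node_x[v], node_y[v])
  for (i in seq_len(nrow(hc$merge))) {
    a <- pos(hc$merge[i, 1])
    b <- pos(hc$merge[i, 2])
    node_x[i] <- (a[1] + b[1]) / 2
    segs[[i]] <- data.frame(
      x = c(a[1], a[1], b[1]),
      xend = c(a[1], b[1], b[1]),
      y = c(a[2], node_y[i], node_y[i]),
      yend = c(node_y[i], node_y[i], b[2])
    )
  }
  segs <- do.call(rbind, segs)
  labs <- data.frame(x = xpos, y = 0, label = hc$labels)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       angle = 90, hjust = 1.1, size = 2.5) +
    ggplot2::scale_y_continuous("merge height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.title.x = ggplot2::element_blank())
}

#' Barchart of ranked match distances
#'
#' @param ranking A ranking tibble (from [run_type1()]/[run_type2()]).
#' @return A ggplot, one bar per match, faceted by query.
#' @export
plot_ranking <- function(ranking) {
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = stats::reorder(.data$match_id,
                                                  .data$rank),
                               y = .data$distance,
                               fill = .data$ecosystem)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~query_id, scales = "free_x") +
    ggplot2::labs(x = "match", y = "distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Composition-comparison barchart
#'
#' Paired bars per taxon (query beside match), taxa ordered by query
#' fraction, faceted by taxonomic rank.
#'
#' @param comparison Tibble from [composition_comparison()].
#' @return A ggplot.
#' @export
plot_composition <- function(comparison) {
  long <- tidyr::pivot_longer(comparison,
                              cols = c("query_fraction", "match_fraction"),
                              names_to = "sample", values_to = "fraction")
  long$sample <- sub("_fraction", "", long$sample)
  long$taxon <- factor(long$taxon, levels = unique(comparison$taxon))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$taxon, y = .data$fraction,
                                     fill = .data$sample)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~rank, scales = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
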