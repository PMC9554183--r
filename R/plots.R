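# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_segment geom_point
#'   geom_text labs theme_minimal scale_y_continuous coord_flip
#' @export
ggplot2::autoplot

#' Plot the discovery funnel of a pipeline report
#'
#' @param object A `cas13_report` from [run_discovery()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cas13_report
#' @export
autoplot.cas13_report <- function(object, ...) {
  counts <- mutate(object$counts,
                   stage = factor(.data$stage, levels = rev(.data$stage)))
  ggplot(counts, aes(x = .data$stage, y = .data$n)) +
    geom_col(fill = "steelblue") +
    geom_text(aes(label = .data$n), hjust = -0.2, size = 3) +
    coord_flip() +
    labs(x = NULL, y = "features remaining",
         title = "Cas13 discovery funnel") +
    theme_minimal()
}

upgma_layout <- function(tree) {
  leaf_x <- numeric(0)
  order_leaves <- function(node) {
    if (node < 0) return(tree$ids[-node])
    row <- tree$merges[tree$merges$node == node, ]
    c(order_leaves(row$left), order_leaves(row$right))
  }
  leaves <- order_leaves(tree$merges$node[nrow(tree$merges)])
  leaf_pos <- setNames(seq_along(leaves), leaves)
  node_xy <- function(node) {
    if (node < 0) {
      return(c(x = unname(leaf_pos[tree$ids[-node]]), y = 0))
    }
    row <- tree$merges[tree$merges$node == node, ]
    l <- node_xy(row$left); r <- node_xy(row$right)
    c(x = (l["x"] + r["x"]) / 2, y = row$height)
  }
  segs <- list()
  for (k in seq_len(nrow(tree$merges))) {
    row <- tree$merges[k, ]
    l <- node_xy(row$left); r <- node_xy(row$right)
    segs[[k]] <- tibble(
      x = c(l["x"], r["x"], l["x"]),
      xend = c(l["x"], r["x"], r["x"]),
      y = c(l["y"], r["y"], row$height),
      yend = c(row$height, row$height, row$height)
    )
  }
  list(segments = bind_rows(segs),
       leaves = tibble(id = leaves, x = seq_along(leaves), y = 0))
}

#' Plot a UPGMA dendrogram
#'
#' @param object A `cas13_upgma` tree.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cas13_upgma
#' @export
autoplot.cas13_upgma <- function(object, ...) {
  lay <- upgma_layout(object)
  ggplot() +
    geom_segment(data = lay$segments,
                 aes(x = .data$x, xend = .data$xend,
                     y = .data$y, yend = .data$yend)) +
    geom_text(data = lay$leaves,
              aes(x = .data$x, y = .data$y, label = .data$id),
              angle = 90, hjust = 1.05, size = 2.8) +
    scale_y_continuous(limits = c(-object$root_height * 0.6, NA)) +
    labs(x = NULL, y = "height (distance / 2)",
         title = "UPGMA subtype dendrogram") +
    theme_minimal()
}

#' Plot HEPN motif architectures along protein lengths
#'
#' One horizontal bar per protein with its R-X4-H motif positions marked;
#' the visual analogue of a domain-architecture schematic.
#'
#' @param annotations A tibble from [annotate_hepn()].
#' @return A ggplot.
#' @export
plot_hepn_architecture <- function(annotations) {
  stopifnot(is.data.frame(annotations))
  motifs <- annotations |>
    select("protein_id", "hits") |>
    tidyr::unnest("hits")
  ggplot(annotations, aes(y = .data$protein_id)) +
    geom_segment(aes(x = 0, xend = .data$protein_len,
                     yend = .data$protein_id), linewidth = 3,
                 colour = "grey80") +
    geom_point(data = motifs,
               aes(x = .data$start, y = .data$protein_id),
               colour = "firebrick", size = 2) +
    labs(x = "residue", y = NULL,
         title = "HEPN (R-X4-H) motif architecture") +
    theme_minimal()
}

#' Plot per-column conservation of a DR profile
#'
#' @param object A `dr_profile` from [dr_consensus()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dr_profile
#' @export
autoplot.dr_profile <- function(object, ...) {
  df <- tibble(
    pos = seq_along(object$per_column_conservation),
    conservation = object$per_column_conservation,
    base = strsplit(object$consensus, "", fixed = TRUE)[[1]]
  )
  ggplot(df, aes(x = .data$pos, y = .data$conservation)) +
    geom_col(fill = "darkgreen", alpha = 0.6) +
    geom_text(aes(label = .data$base, y = 0.02), size = 2.5, vjust = 0) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "DR position", y = "column conservation",
         title = "Direct-repeat consensus conservation") +
    theme_minimal()
}
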