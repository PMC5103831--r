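# ggplot2 views of the main result types.

#' Plot a U-matrix as a heat map
#'
#' Dark valleys are candidate genome bins, bright ridges their boundaries.
#' Remember the grid is toroidal: structure continues across the edges.
#'
#' @param object A `umatrix` tibble from [compute_umatrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.umatrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$c, y = .data$r,
                                       fill = .data$u)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "U") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row",
                  title = "U-matrix (toroidal grid)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.umatrix
#' @param model A trained `esom`.
#' @export
plot_umatrix <- function(model, ...) {
  u <- if (inherits(model, "esom")) compute_umatrix(model) else model
  autoplot.umatrix(u, ...)
}

#' Ordination scatter plot
#'
#' First two principal coordinates, optionally colored by a per-sample
#' grouping (e.g. sampling depth).
#'
#' @param object A `pcoa_ordination`.
#' @param groups Optional named vector or tibble (`sample_id`, `group`)
#'   used to color points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pcoa_ordination <- function(object, groups = NULL, ...) {
  d <- object$coordinates
  pct <- 100 * object$proportion_explained
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      d <- dplyr::left_join(d, groups, by = "sample_id")
    } else {
      d$group <- unname(groups[d$sample_id])
    }
  }
  p <- if (is.null(groups))
    ggplot2::ggplot(d, ggplot2::aes(x = .data$Axis1, y = .data$Axis2))
  else
    ggplot2::ggplot(d, ggplot2::aes(x = .data$Axis1, y = .data$Axis2,
                                    color = .data$group))
  p +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", pct[1]),
      y = sprintf("PCo2 (%.1f%%)", if (length(pct) > 1) pct[2] else NA),
      title = "Bray-Curtis PCoA") +
    ggplot2::theme_minimal()
}

#' Stacked phylum abundance bars
#'
#' Percent community composition per sample, stacked by phylum — the
#' standard community-profile bar chart.
#'
#' @param phylum_abundance Tibble from [phylum_rollup()].
#' @return A ggplot.
#' @export
plot_phylum_bars <- function(phylum_abundance) {
  sample_cols <- setdiff(names(phylum_abundance), "taxon")
  long <- tidyr::pivot_longer(phylum_abundance,
                              dplyr::all_of(sample_cols),
                              names_to = "sample_id", values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$pct,
                                     fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative abundance (%)", fill = "phylum") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
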