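# ggplot2 views of each result type. These are working plots (review,
# vignettes), not publication graphics.

#' @describeIn assess_pollution Bar chart of PN and RI per site.
#' @param object A `pollution_scores` object.
#' @method autoplot pollution_scores
#' @export
autoplot.pollution_scores <- function(object, ...) {
  long <- object$site |>
    select("site", "pn", "ri") |>
    tidyr::pivot_longer(c("pn", "ri"), names_to = "index", values_to = "value") |>
    mutate(index = toupper(.data$index))
  ggplot(long, aes(x = .data$site, y = .data$value)) +
    geom_col(fill = "grey35") +
    facet_wrap(~.data$index, scales = "free_y") +
    labs(x = NULL, y = "index value",
         title = "Pollution indices per site") +
    theme_minimal()
}

#' @describeIn pcoa_ord Ordination scatter of the first two axes.
#' @param object A `pcoa_ord` object.
#' @method autoplot pcoa_ord
#' @export
autoplot.pcoa_ord <- function(object, ...) {
  sc <- tidy(object)
  if (ncol(object$scores) < 2) abort("Need at least two positive axes to plot.")
  pe <- 100 * object$proportion_explained
  ggplot(sc, aes(x = .data$PCo1, y = .data$PCo2)) +
    geom_point(size = 2) +
    ggplot2::geom_text(aes(label = .data$sample), vjust = -0.8, size = 3) +
    labs(x = sprintf("PCo1 (%.2f%%)", pe[1]),
         y = sprintf("PCo2 (%.2f%%)", pe[2]),
         title = "Principal coordinate analysis") +
    theme_minimal()
}

#' @describeIn rda_fit Triplot-style view: site scores and variable arrows.
#' @param object An `rda_fit` object.
#' @method autoplot rda_fit
#' @export
autoplot.rda_fit <- function(object, ...) {
  if (ncol(object$scores) < 2) abort("Need at least two canonical axes to plot.")
  sc <- tidy(object)
  pe <- 100 * object$proportion_explained
  arrows <- as_tibble(object$biplot) |>
    mutate(variable = rownames(object$biplot))
  mult <- max(abs(sc$RDA1), abs(sc$RDA2))
  ggplot(sc, aes(x = .data$RDA1, y = .data$RDA2)) +
    geom_point(size = 2) +
    ggplot2::geom_text(aes(label = .data$sample), vjust = -0.8, size = 3) +
    ggplot2::geom_segment(data = arrows,
                          aes(x = 0, y = 0, xend = .data$RDA1 * mult,
                              yend = .data$RDA2 * mult),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "firebrick") +
    ggplot2::geom_text(data = arrows,
                       aes(x = .data$RDA1 * mult, y = .data$RDA2 * mult,
                           label = .data$variable),
                       colour = "firebrick", vjust = -0.6, size = 3) +
    labs(x = sprintf("RDA1 (%.2f%%)", pe[1]),
         y = sprintf("RDA2 (%.2f%%)", pe[2]),
         title = "Redundancy analysis") +
    theme_minimal()
}

#' Rarefaction curves
#' @param rc Tibble from [rarefaction_curve()].
#' @return A ggplot object.
#' @export
plot_rarefaction <- function(rc) {
  ggplot(rc, aes(x = .data$depth, y = .data$expected_species,
                 colour = .data$sample)) +
    geom_line() +
    labs(x = "subsampling depth (reads)", y = "expected observed species",
         title = "Rarefaction (dilution) curves") +
    theme_minimal()
}

#' Correlation heatmap with significance stars
#'
#' Tile heatmap of a [spearman_matrix()] (or [pearson_matrix()]) result,
#' rows and columns ordered by [cluster_order()], stars printed per cell.
#'
#' @param result A `cor_result`.
#' @return A ggplot object.
#' @export
plot_cor_heatmap <- function(result) {
  ord <- cluster_order(result)
  rn <- names(result)[1]
  cn <- names(result)[2]
  df <- as_tibble(result) |>
    mutate("{rn}" := factor(.data[[rn]], levels = ord$row_order),
           "{cn}" := factor(.data[[cn]], levels = ord$col_order))
  ggplot(df, aes(x = .data[[cn]], y = .data[[rn]], fill = .data$rho)) +
    geom_tile() +
    geom_text(aes(label = .data$stars), size = 3) +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "rho",
         title = "Correlation heatmap (* p<0.05, ** p<0.01)") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Variance partitioning fractions
#' @param part A `vpa_result`.
#' @return A ggplot object.
#' @export
plot_vpa <- function(part) {
  df <- tidy(part)
  ggplot(df, aes(x = stats::reorder(.data$fraction, .data$adj_r2),
                 y = .data$adj_r2)) +
    geom_col(fill = "grey35") +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "adjusted R2 fraction",
         title = "Variance partitioning") +
    theme_minimal()
}
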