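#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   geom_tile labs facet_wrap scale_fill_manual coord_fixed theme_minimal
NULL

.layer_fill <- c(basal = "#c0392b", spinous = "#27ae60", granular = "#2980b9")

#' @export
ggplot2::autoplot

#' Plot a lineage trajectory
#'
#' @param object an `epistrat_lineage_sim` from [simulate_lineage()].
#' @param ... unused.
#' @return a ggplot of the four compartment sizes over time.
#' @export
autoplot.epistrat_lineage_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("c0", "c1", "c2", "c3"),
                              names_to = "compartment", values_to = "cells")
  ggplot(long, aes(x = .data$t, y = .data$cells,
                   colour = .data$compartment)) +
    geom_line() +
    labs(x = "time (h)", y = "population (cells)", colour = NULL) +
    theme_minimal()
}

#' Plot per-slice stratification metrics
#'
#' @param object an `epistrat_metrics` from [metrics_report()].
#' @param ... unused.
#' @return a ggplot of the Sharpness Index profile along z.
#' @export
autoplot.epistrat_metrics <- function(object, ...) {
  ggplot(object$slices, aes(x = .data$si, y = .data$z)) +
    geom_col(orientation = "y", fill = "grey40", width = 3) +
    labs(x = "Sharpness Index", y = "slice height (µm)",
         title = sprintf("t = %.0f h", object$time)) +
    theme_minimal()
}

#' Plot cell counts over a run
#'
#' @param object an `epistrat_run` from [run_simulation()].
#' @param ... unused.
#' @return a ggplot of per-type counts over time.
#' @export
autoplot.epistrat_run <- function(object, ...) {
  long <- tidyr::pivot_longer(object$snapshots, c("C0", "C1", "C2", "C3"),
                              names_to = "type", values_to = "cells")
  ggplot(long, aes(x = .data$time, y = .data$cells, colour = .data$type)) +
    geom_line() +
    labs(x = "time (h)", y = "cells", colour = NULL,
         title = sprintf("%s variant, %s", object$config$variant,
                         object$config$genotype)) +
    theme_minimal()
}

#' Plot a rasterized slice image
#'
#' @param object an `epistrat_slice_image` from [rasterize_slice()].
#' @param ... unused.
#' @return a ggplot tile map of the layer labels.
#' @export
autoplot.epistrat_slice_image <- function(object, ...) {
  df <- expand.grid(x = seq_len(nrow(object$img)), y = seq_len(ncol(object$img)))
  df$label <- c("basal", "spinous", "granular")[as.vector(object$img) + 1L]
  df$label[as.vector(object$mask)] <- df$label[as.vector(object$mask)]
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$label)) +
    geom_tile(colour = "white") +
    scale_fill_manual(values = .layer_fill, na.value = "grey80") +
    coord_fixed() +
    labs(title = sprintf("slice z = %.1f µm", object$z), fill = NULL) +
    theme_minimal()
}

#' Side view of a tissue
#'
#' @param tissue an `epistrat_tissue`.
#' @param by plot `"cell"` centroids or all `"element"` positions.
#' @return a ggplot x-z scatter coloured by layer.
#' @export
plot_tissue <- function(tissue, by = c("cell", "element")) {
  by <- match.arg(by)
  df <- if (by == "cell") tissue_cells(tissue) else as_tibble(tissue)
  df$layer <- c("basal", "spinous", "spinous", "granular")[
    match(df$cell_type, c("C0", "C1", "C2", "C3"))]
  ggplot(df, aes(x = .data$x, y = .data$z, colour = .data$layer)) +
    geom_point(size = if (by == "cell") 2 else 0.8, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = .layer_fill) +
    coord_fixed() +
    labs(x = "x (µm)", y = "z (µm)", colour = NULL,
         title = sprintf("t = %.0f h", tissue$time)) +
    theme_minimal()
}
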