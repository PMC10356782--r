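#' Plot registration QC
#'
#' Per-section Dice coefficient of the registered tissue mask against the
#' reference, with the adjacent-pair NCC overlaid.
#'
#' @param object an `mx_registration`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mx_registration <- function(object, ...) {
  qc <- object$qc
  adj <- object$adjacent
  adj$mid <- (adj$index_a + adj$index_b) / 2
  ggplot2::ggplot(qc, ggplot2::aes(x = .data$retained_index,
                                   y = .data$dsc)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = adj,
                        ggplot2::aes(x = .data$mid, y = .data$ncc),
                        colour = "steelblue", shape = 17) +
    ggplot2::labs(x = "retained section index",
                  y = "DSC (points) / adjacent NCC (triangles)",
                  title = "Registration quality") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Compare 2D and 3D vessel distances
#'
#' Violin-style comparison of the same-section (2D) and full-volume (3D)
#' immune-cell-to-vessel distance distributions.
#'
#' @param distances tibble from [distance_records()].
#' @return A ggplot.
#' @export
plot_distance_comparison <- function(distances) {
  ok <- distances[!distances$no_target_in_section, ]
  long <- tidyr::pivot_longer(ok, c("d2d_um", "d3d_um"),
                              names_to = "mode", values_to = "distance_um")
  long$mode <- ifelse(long$mode == "d2d_um", "2D", "3D")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mode,
                                     y = .data$distance_um,
                                     fill = .data$mode)) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA,
                          show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "distance to nearest vessel (µm)",
                  title = "Immune cell to vessel distances") +
    ggplot2::theme_minimal()
}

#' Plot cluster-density counts
#'
#' Distribution of neighbour counts around each index cell for each radius,
#' 2D versus 3D.
#'
#' @param clusters tibble from [cluster_density()].
#' @return A ggplot.
#' @export
plot_cluster_density <- function(clusters) {
  long <- tidyr::pivot_longer(clusters, c("count2d", "count3d"),
                              names_to = "mode", values_to = "count")
  long$mode <- ifelse(long$mode == "count2d", "2D", "3D")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$radius_um),
                                     y = .data$count,
                                     fill = .data$mode)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(0.8)) +
    ggplot2::labs(x = "radius (µm)", y = "neighbours per index cell",
                  fill = NULL, title = "Immune cluster density") +
    ggplot2::theme_minimal()
}
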