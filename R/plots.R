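# ggplot2 visualisations of networks, oxygen fields and KTC solutions.

#' Plot a vascular network (2D projection)
#'
#' Projects segments onto the x-y plane, coloured by wall type with line
#' width proportional to radius; root nodes are marked.
#'
#' @param object A [vascular_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vascular_network <- function(object, ...) {
  seg <- tidy(object)
  roots <- dplyr::filter(object$nodes, .data$kind != "interior")
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, colour = .data$wall_type,
                   linewidth = .data$radius), alpha = 0.8) +
    ggplot2::geom_point(data = roots,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$kind), size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 2), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' Plot a tissue oxygen field slice
#'
#' Mid-depth (or chosen) z slice of the solved tissue pO2 field.
#'
#' @param object A [solve_coupled()] result.
#' @param k Slice index (default mid-depth).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oxygen_solution <- function(object, k = NULL, ...) {
  g <- object$grid
  if (is.null(k)) k <- ceiling(g$shape[3] / 2)
  sl <- g$po2[, , k]
  df <- tidyr::expand_grid(i = seq_len(g$shape[1]), j = seq_len(g$shape[2]))
  df$po2 <- as.vector(sl)
  df$x <- (df$i - 0.5) * g$spacing
  df$y <- (df$j - 0.5) * g$spacing
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$po2)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "pO2 (mm Hg)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = sprintf("tissue pO2, slice k = %d", k)) +
    ggplot2::theme_minimal()
}

#' Plot a Krogh-cylinder solution
#'
#' Axial mixed-lumen and wall pO2 profiles with the local Sherwood number.
#'
#' @param object A [solve_ktc()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ktc_solution <- function(object, ...) {
  ax <- tidyr::pivot_longer(object$axial[, c("z", "lumen_po2", "wall_po2")],
                            -"z", names_to = "series", values_to = "po2")
  ggplot2::ggplot(ax, ggplot2::aes(x = .data$z, y = .data$po2,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (um)", y = "pO2 (mm Hg)") +
    ggplot2::theme_minimal()
}
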