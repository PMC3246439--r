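# Plotting is a thin, untested presentation layer over the result tibbles.

#' Plot outlines
#'
#' @param outlines An outline tibble.
#' @param ncol Facet columns.
#' @return A ggplot object.
#' @export
plot_outlines <- function(outlines, ncol = NULL) {
  outlines <- as_outlines(outlines)
  ggplot2::ggplot(outlines, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::geom_path(
      data = dplyr::slice(dplyr::group_by(outlines, .data$specimen_id),
        c(dplyr::n(), 1)),
      linetype = "solid"
    ) +
    ggplot2::facet_wrap(~specimen_id, ncol = ncol, scales = "free") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Score scatter of a shape space with optional group ellipses
#'
#' @param object A `shape_space`.
#' @param components Two component indices to plot.
#' @param groups Optional data frame with `specimen_id` and a `group`
#'   column; when given, per-group confidence ellipses are drawn.
#' @param level Ellipse confidence level.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shape_space <- function(object, components = c(1, 2),
                                 groups = NULL, level = 0.95, ...) {
  pcs <- paste0("PC", components)
  df <- object$scores
  lab <- sprintf("%s (%.1f%%)", pcs,
    100 * object$variance_fraction[components])
  p <- ggplot2::ggplot(df,
    ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]]))
  if (!is.null(groups)) {
    df <- dplyr::left_join(df, groups, by = "specimen_id")
    ell <- confidence_ellipse(df, vars = pcs, level = level,
      group = "group")
    poly <- dplyr::bind_rows(purrr::map(seq_len(nrow(ell)), function(i) {
      xy <- ellipse_polygon(ell[i, ])
      tibble::tibble(group = ell$group[i], x = xy[, 1], y = xy[, 2])
    }))
    p <- ggplot2::ggplot(df,
      ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]],
        colour = .data$group)) +
      ggplot2::geom_path(
        data = poly,
        ggplot2::aes(x = .data$x, y = .data$y, colour = .data$group),
        inherit.aes = FALSE
      )
  }
  p +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
}

#' Extreme-shape glyphs for the leading components
#'
#' @param space A `shape_space`.
#' @param components Component indices.
#' @param n_points Points per reconstructed outline.
#' @return A ggplot object.
#' @export
plot_extreme_shapes <- function(space, components = 1:3, n_points = 256) {
  shapes <- dplyr::bind_rows(lapply(components, function(k) {
    df <- extreme_shapes(space, k, n_points = n_points)
    df$component <- paste0("PC", k)
    df$end <- sub("^PC[0-9]+_", "", df$specimen_id)
    df
  }))
  ggplot2::ggplot(shapes,
    ggplot2::aes(x = .data$x, y = .data$y, colour = .data$end)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~component) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, colour = "extreme")
}

#' Score spread by length class as a bar-and-range plot
#'
#' @param spread A tibble from [spread_by_length()].
#' @return A ggplot object.
#' @export
plot_spread <- function(spread) {
  ggplot2::ggplot(spread, ggplot2::aes(x = factor(.data$bin))) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$median - .data$iqr / 2,
        ymax = .data$median + .data$iqr / 2),
      width = 0.3
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median), size = 2) +
    ggplot2::labs(x = "length class", y = "score") +
    ggplot2::theme_minimal()
}
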