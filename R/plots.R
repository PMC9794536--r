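#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an experiment curve
#'
#' Force curves (`F_nN`) are drawn against indentation depth during
#' loading or against time otherwise; aspiration curves (`Lp_um`) against
#' time.
#'
#' @param object A `cyto_curve`.
#' @param x_var `"auto"`, `"t"` or `"delta"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cyto_curve
#' @export
autoplot.cyto_curve <- function(object, x_var = c("auto", "t", "delta"), ...) {
  x_var <- match.arg(x_var)
  df <- as_tibble(object)
  meta <- curve_meta(object)
  y <- if ("F_nN" %in% names(df)) "F_nN" else "Lp_um"
  x <- switch(x_var,
    t = "t_s",
    delta = "delta_um",
    auto = if ("t_s" %in% names(df)) "t_s" else "delta_um"
  )
  labs_y <- if (y == "F_nN") "Force (nN)" else "Aspirated length (µm)"
  labs_x <- if (x == "t_s") "Time (s)" else "Indentation (µm)"
  ggplot2::ggplot(df, ggplot2::aes(.data[[x]], .data[[y]])) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(
      x = labs_x, y = labs_y,
      title = paste(
        c(meta$model, meta$kind),
        collapse = " "
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fit against its data
#'
#' @param object A `cyto_fit`.
#' @param ... Unused.
#' @return A ggplot object overlaying the fitted curve on the data
#'   points.
#' @method autoplot cyto_fit
#' @export
autoplot.cyto_fit <- function(object, ...) {
  df <- as_tibble(object$data)
  xcol <- if ("t_s" %in% names(df)) "t_s" else "delta_um"
  ycol <- if ("F_nN" %in% names(df)) "F_nN" else "Lp_um"
  df$.fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(.data[[xcol]])) +
    ggplot2::geom_point(ggplot2::aes(y = .data[[ycol]]), size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "red", linewidth = 0.7) +
    ggplot2::labs(
      x = if (xcol == "t_s") "Time (s)" else "Indentation (µm)",
      y = if (ycol == "F_nN") "Force (nN)" else "Aspirated length (µm)",
      title = paste("Fitted", object$model_kind, "model")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a tensegrity graph projection
#'
#' Orthographic projection of nodes and members onto a coordinate plane;
#' struts are drawn heavy, cables light.
#'
#' @param g A `tensegrity` object (or the `nodes`/`members` of a
#'   `tenseg_solution`).
#' @param plane `"xz"`, `"yz"` or `"xy"`.
#' @return A ggplot object.
#' @export
plot_tensegrity <- function(g, plane = c("xz", "yz", "xy")) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  cols <- paste0(ax, "_um")
  nodes <- g$nodes
  seg <- g$members |>
    mutate(
      x0 = nodes[[cols[1]]][.data$i], y0 = nodes[[cols[2]]][.data$i],
      x1 = nodes[[cols[1]]][.data$j], y1 = nodes[[cols[2]]][.data$j]
    )
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
        colour = .data$kind, linewidth = .data$kind
      )
    ) +
    ggplot2::scale_linewidth_manual(values = c(cable = 0.4, strut = 1.4)) +
    ggplot2::scale_colour_manual(values = c(cable = "grey40", strut = "firebrick")) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = paste0(ax[1], " (µm)"), y = paste0(ax[2], " (µm)")
    ) +
    ggplot2::theme_minimal()
}
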