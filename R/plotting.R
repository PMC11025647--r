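#' Plot a fitted difference topography
#'
#' Renders a [difference_surface()] lattice as a scalp map: the mean
#' amplitude difference as a filled raster inside the head outline,
#' with points whose posterior sign probability falls below the mask
#' level drawn grey.
#'
#' @param td a `topo_difference`.
#' @param layout optional [make_layout()] layout whose electrodes are
#'   overplotted.
#' @return a ggplot object.
#' @export
plot_topo_difference <- function(td, layout = NULL) {
  stopifnot(inherits(td, "topo_difference"))
  df <- as.data.frame(td)
  df$value <- ifelse(df$masked, NA_real_, df$mean_diff)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", na.value = "grey80",
                                  name = "ΔµV") +
    ggplot2::annotate("path",
                      x = cos(seq(0, 2 * pi, length.out = 200)),
                      y = sin(seq(0, 2 * pi, length.out = 200))) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s difference (levels %s vs %s)",
                                  attr(td, "predictor"),
                                  attr(td, "levels")[1],
                                  attr(td, "levels")[2])) +
    ggplot2::theme_void()
  if (!is.null(layout)) {
    p <- p + ggplot2::geom_point(data = as.data.frame(layout),
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 size = 0.5)
  }
  p
}

#' Plot observed grand-mean difference topographies
#'
#' Scalp maps of the per-electrode grand-mean differences computed by
#' [grand_mean_report()] (reanalysis minus no reanalysis, and
#' high minus low surprisal).
#'
#' @param report data.frame from [grand_mean_report()].
#' @param which `"cond"` or `"surp"`.
#' @return a ggplot object.
#' @export
plot_grand_mean <- function(report, which = c("cond", "surp")) {
  which <- match.arg(which)
  col <- paste0(which, "_diff")
  check_columns(report, c("electrode", "x", "y", col), "report")
  ggplot2::ggplot(report, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::annotate("path",
                      x = cos(seq(0, 2 * pi, length.out = 200)),
                      y = sin(seq(0, 2 * pi, length.out = 200))) +
    ggplot2::geom_point(ggplot2::aes(fill = .data[[col]]), shape = 21,
                        size = 6) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", name = "ΔµV") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(title = if (which == "cond")
      "Grand mean: reanalysis - no reanalysis" else
        "Grand mean: high - low surprisal")
}
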