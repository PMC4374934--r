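# Purple (low) to red (high) scale used for the published density and
# neighbour maps: rainbow path red->purple, reversed.
density_palette <- function(n) {
  rev(grDevices::rainbow(n, start = 0, end = 0.8))
}

#' @export
plot.isodensity_grid <- function(x, ...) {
  graphics::image(x = x$x_edges, y = x$y_edges, z = t(x$density),
                  col = density_palette(x$n_colours),
                  zlim = c(0, x$scale_max),
                  xlab = "x (mm, nasal +)", ylab = "y (mm, superior +)",
                  asp = 1, useRaster = TRUE, ...)
  invisible(x)
}

#' @export
plot.neighbour_map <- function(x, ...) {
  pal <- density_palette(attr(x, "max_colour_count") + 1L)
  graphics::plot(x$x_mm, x$y_mm, col = pal[x$colour_bin], pch = 16,
                 cex = 0.5, asp = 1,
                 xlab = "x (mm, nasal +)", ylab = "y (mm, superior +)", ...)
  invisible(x)
}
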