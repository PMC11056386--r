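# Base-graphics display methods. Images are drawn in object-space
# micrometers with y increasing downward disabled (standard image
# orientation), using a perceptually monotone gray ramp.

plot_matrix <- function(m, pixel_size, main, zlab = "rad", ...) {
  x <- (seq_len(ncol(m)) - 1) * pixel_size
  y <- (seq_len(nrow(m)) - 1) * pixel_size
  graphics::image(x = x, y = y, z = t(m), asp = 1, useRaster = TRUE,
                  col = grDevices::gray.colors(256, 0, 1),
                  xlab = "x (um)", ylab = "y (um)", main = main, ...)
  invisible(NULL)
}

#' @export
plot.phase_phantom <- function(x, ...) {
  plot_matrix(x$phase, x$grid$pixel_size,
              sprintf("phase phantom (max %.3g rad)", max(x$phase)), ...)
}

#' @export
plot.interferogram <- function(x, ...) {
  plot_matrix(x$intensity, x$grid$pixel_size,
              sprintf("interferogram, bias %.3g rad", x$bias), ...)
}

#' @export
plot.gradient_phase_image <- function(x, ...) {
  plot_matrix(x$grad_phase, x$grid$pixel_size,
              sprintf("gradient phase (%d-step)", x$nsteps), ...)
}

#' @export
plot.phase_image <- function(x, ...) {
  plot_matrix(x$phase, x$grid$pixel_size,
              sprintf("quantitative phase (%s)", x$method), ...)
}

#' @export
plot.profile_fit <- function(x, ...) {
  xs <- x$data$position; ys <- x$data$value
  graphics::plot(xs, ys, pch = 16, cex = 0.6, xlab = "position (um)",
                 ylab = "phase (rad)",
                 main = sprintf("Gaussian fit: FWHM %.3g um", x$fwhm), ...)
  xx <- seq(min(xs), max(xs), length.out = 400)
  graphics::lines(xx, x$amplitude * exp(-(xx - x$center)^2 / (2 * x$sigma^2)) +
                    x$offset, col = "red3", lwd = 2)
  invisible(x)
}
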