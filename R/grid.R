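#' Pixel grid of an image in object space
#'
#' Defines the sampling of every image handled by the package: `ny` rows
#' (the y axis) by `nx` columns (the x axis, which is also the shear /
#' gradient axis), with square pixels of side `pixel_size` micrometers.
#' The object-space coordinate of array element `[i, j]` is
#' `x = (j - 1) * pixel_size`, `y = (i - 1) * pixel_size`, so the origin
#' sits on the first pixel center.
#'
#' @param ny,nx Number of rows / columns (each at least 8).
#' @param pixel_size Object-space pixel pitch in micrometers (> 0).
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(64, 64, 0.1)
#' range(grid_x(g))
#' @export
image_grid <- function(ny, nx, pixel_size) {
  ny <- as.integer(ny); nx <- as.integer(nx)
  if (ny < 8 || nx < 8) stop("image_grid: ny and nx must be >= 8")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("image_grid: pixel_size must be > 0")
  structure(list(ny = ny, nx = nx, pixel_size = pixel_size),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d px, %.4g um/px (%.3g x %.3g um)\n",
              x$ny, x$nx, x$pixel_size,
              x$nx * x$pixel_size, x$ny * x$pixel_size))
  invisible(x)
}

#' @rdname image_grid
#' @param grid An `image_grid`.
#' @export
grid_x <- function(grid) (seq_len(grid$nx) - 1) * grid$pixel_size

#' @rdname image_grid
#' @export
grid_y <- function(grid) (seq_len(grid$ny) - 1) * grid$pixel_size

# Matrices of x and y coordinates (ny x nx), used by the phantom generators.
grid_xy <- function(grid) {
  list(X = matrix(grid_x(grid), grid$ny, grid$nx, byrow = TRUE),
       Y = matrix(grid_y(grid), grid$ny, grid$nx))
}

same_grid <- function(a, b, tol = 1e-9) {
  a$ny == b$ny && a$nx == b$nx && abs(a$pixel_size - b$pixel_size) <= tol
}

stopifnot_grid <- function(grid) {
  if (!inherits(grid, "image_grid")) stop("expected an 'image_grid' object")
  invisible(grid)
}
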