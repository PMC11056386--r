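# TIFF + sidecar I/O.
#
# Images are stored as (multi-page) 32-bit TIFF, linearly rescaled to the
# [0, 1] sample range the TIFF writer expects; the physical range (zmin,
# zmax), pixel size, wavelength and acquisition metadata travel in a
# plain-text key-value sidecar `<path>.yml`. Reading restores the physical
# values. Validity masks accompany gradient images as 8-bit TIFFs.

sidecar_path <- function(path) paste0(path, ".yml")

write_pages_tiff <- function(pages, path, meta) {
  zmin <- min(vapply(pages, min, numeric(1)))
  zmax <- max(vapply(pages, max, numeric(1)))
  scaled <- lapply(pages, function(p) {
    if (zmax > zmin) (p - zmin) / (zmax - zmin) else p * 0
  })
  tiff::writeTIFF(if (length(scaled) == 1) scaled[[1]] else scaled,
                  path, bits.per.sample = 32L, compression = "none")
  meta$zmin <- zmin; meta$zmax <- zmax
  meta$ny <- nrow(pages[[1]]); meta$nx <- ncol(pages[[1]])
  meta$pages <- length(pages)
  yaml::write_yaml(meta, sidecar_path(path), precision = 12L)
  invisible(path)
}

read_pages_tiff <- function(path, need_meta = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc)) yaml::read_yaml(sc) else NULL
  if (need_meta && (is.null(meta) || is.null(meta$pixel_size)))
    stop("missing sidecar metadata (pixel_size) for ", path,
         "; pass override metadata to read anyway")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    if (!is.null(meta$zmin) && meta$zmax > meta$zmin)
      p * (meta$zmax - meta$zmin) + meta$zmin
    else p
  })
  list(pages = pages, meta = meta)
}

optics_to_meta <- function(optics) {
  list(wavelength = optics$wavelength, na_objective = optics$na_objective,
       na_condenser = optics$na_condenser, magnification = optics$magnification,
       camera_pixel = optics$camera_pixel, shear_distance = optics$shear_distance,
       shear_axis = optics$shear_axis)
}

meta_to_optics <- function(m) {
  optical_config(wavelength = m$wavelength, na_objective = m$na_objective,
                 na_condenser = m$na_condenser %||% 0.30,
                 magnification = m$magnification, camera_pixel = m$camera_pixel,
                 shear_distance = m$shear_distance,
                 shear_axis = unlist(m$shear_axis %||% c(1, 0)))
}

#' Write and read phase phantoms, stacks, and images as TIFF
#'
#' Each writer stores the pixel data as 32-bit TIFF (multi-page for bias
#' series) plus a plain-text key-value sidecar `<path>.yml` holding the
#' physical value range, pixel size, wavelength, and — for stacks — the
#' bias schedule and optical configuration; page order is bias order.
#' Readers refuse files whose sidecar metadata is missing.
#'
#' @param phantom,stack,grad,phase The object to write.
#' @param path Output TIFF path.
#' @return The path, invisibly (writers); the reconstructed object
#'   (readers).
#' @name grom_io
NULL

#' @rdname grom_io
#' @export
write_phantom <- function(phantom, path) {
  write_pages_tiff(list(phantom$phase), path,
                   list(type = "phase_phantom",
                        pixel_size = phantom$grid$pixel_size,
                        wavelength = phantom$wavelength))
}

#' @rdname grom_io
#' @export
read_phantom <- function(path) {
  r <- read_pages_tiff(path)
  if (is.null(r$meta$wavelength)) stop("phantom sidecar lacks wavelength")
  new_phase_phantom(image_grid(r$meta$ny, r$meta$nx, r$meta$pixel_size),
                    r$pages[[1]], r$meta$wavelength)
}

#' @rdname grom_io
#' @export
write_stack <- function(stack, path) {
  meta <- list(type = "interferogram_stack",
               pixel_size = stack$grid$pixel_size,
               wavelength = stack$optics$wavelength,
               biases = stack$schedule$biases,
               deltas = stack$schedule$deltas,
               optics = optics_to_meta(stack$optics))
  write_pages_tiff(stack_intensities(stack), path, meta)
}

#' @rdname grom_io
#' @export
read_stack <- function(path) {
  r <- read_pages_tiff(path)
  m <- r$meta
  if (is.null(m$biases)) stop("stack sidecar lacks the bias schedule")
  if (length(r$pages) != length(m$biases))
    stop(sprintf("page count (%d) does not match bias schedule length (%d)",
                 length(r$pages), length(m$biases)))
  grid <- image_grid(m$ny, m$nx, m$pixel_size)
  optics <- meta_to_optics(m$optics)
  frames <- lapply(seq_along(r$pages), function(i)
    new_interferogram(grid, r$pages[[i]], m$biases[i]))
  structure(list(frames = frames,
                 schedule = bias_schedule(biases = unlist(m$biases),
                                          deltas = unlist(m$deltas)),
                 optics = optics, grid = grid),
            class = "interferogram_stack")
}

#' @rdname grom_io
#' @export
write_gradient <- function(grad, path) {
  write_pages_tiff(list(grad$grad_phase), path,
                   list(type = "gradient_phase_image",
                        pixel_size = grad$grid$pixel_size,
                        shear_axis = grad$shear_axis, nsteps = grad$nsteps))
  mask_path <- sub("(\\.tiff?)?$", "_mask.tif", path)
  tiff::writeTIFF(matrix(as.numeric(grad$valid), nrow(grad$valid)),
                  mask_path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname grom_io
#' @export
read_gradient <- function(path) {
  r <- read_pages_tiff(path)
  m <- r$meta
  grid <- image_grid(m$ny, m$nx, m$pixel_size)
  mask_path <- sub("(\\.tiff?)?$", "_mask.tif", path)
  valid <- if (file.exists(mask_path)) tiff::readTIFF(mask_path) > 0.5 else NULL
  new_gradient_phase_image(grid, r$pages[[1]],
                           unlist(m$shear_axis %||% c(1, 0)),
                           m$nsteps %||% NA_integer_, valid)
}

#' @rdname grom_io
#' @export
write_phase <- function(phase, path) {
  write_pages_tiff(list(phase$phase), path,
                   list(type = "phase_image",
                        pixel_size = phase$grid$pixel_size,
                        method = phase$method,
                        background_constant = phase$background_constant))
}

#' @rdname grom_io
#' @export
read_phase <- function(path) {
  r <- read_pages_tiff(path)
  m <- r$meta
  new_phase_image(image_grid(m$ny, m$nx, m$pixel_size), r$pages[[1]],
                  m$method %||% "unknown", m$background_constant %||% 0)
}
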