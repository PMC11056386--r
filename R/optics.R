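#' Optical configuration of the simulated DIC microscope
#'
#' Collects the physical parameters of the imaging system: wavelength,
#' objective and condenser numerical apertures, magnification, camera pixel
#' pitch, and the DIC shear vector. The object-space sampling is
#' `camera_pixel / magnification`; a warning is raised when it fails the
#' Nyquist condition for the objective point spread function (pixel larger
#' than half the PSF FWHM).
#'
#' The shear distance defaults to half the incoherent PSF FWHM
#' (`0.514 * wavelength / na_objective / 2`), reflecting a DIC prism whose
#' beam separation stays below the PSF width; it is a free calibration
#' parameter of the instrument and can be set explicitly.
#'
#' @param wavelength Center wavelength in micrometers.
#' @param na_objective Objective numerical aperture, in (0, 1.5].
#' @param na_condenser Condenser numerical aperture (illumination side).
#' @param magnification Lateral magnification (camera to object).
#' @param camera_pixel Physical camera pixel pitch in micrometers.
#' @param shear_distance Object-space beam separation in micrometers
#'   (default half the PSF FWHM).
#' @param shear_axis Unit vector of the shear direction; `c(1, 0)` (the x /
#'   column axis) or `c(0, 1)` (the y / row axis).
#' @return An object of class `optical_config`.
#' @examples
#' optical_config(0.65, na_objective = 0.75, magnification = 40)
#' @export
optical_config <- function(wavelength = 0.65, na_objective = 0.75,
                           na_condenser = 0.30, magnification = 40,
                           camera_pixel = 1.85, shear_distance = NULL,
                           shear_axis = c(1, 0)) {
  if (!is.finite(wavelength) || wavelength <= 0)
    stop("optical_config: wavelength must be > 0")
  if (!is.finite(na_objective) || na_objective <= 0 || na_objective > 1.5)
    stop("optical_config: na_objective must lie in (0, 1.5]")
  if (magnification <= 0 || camera_pixel <= 0)
    stop("optical_config: magnification and camera_pixel must be > 0")
  if (length(shear_axis) != 2 || abs(sqrt(sum(shear_axis^2)) - 1) > 1e-9)
    stop("optical_config: shear_axis must be a unit vector")
  fwhm <- psf_fwhm(wavelength, na_objective)
  if (is.null(shear_distance)) shear_distance <- fwhm / 2
  if (!is.finite(shear_distance) || shear_distance <= 0)
    stop("optical_config: shear_distance must be > 0")
  px <- camera_pixel / magnification
  if (px > fwhm / 2)
    warning(sprintf(
      "object-space pixel %.3g um exceeds Nyquist limit %.3g um (PSF FWHM / 2)",
      px, fwhm / 2))
  structure(list(wavelength = wavelength, na_objective = na_objective,
                 na_condenser = na_condenser, magnification = magnification,
                 camera_pixel = camera_pixel, shear_distance = shear_distance,
                 shear_axis = as.numeric(shear_axis)),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<optical_config> lambda = %g um, NA %g/%g (obj/cond), %gx, ",
    "pixel %g um (%.4g um object), shear %.4g um along (%g, %g)\n"),
    x$wavelength, x$na_objective, x$na_condenser, x$magnification,
    x$camera_pixel, object_pixel(x), x$shear_distance,
    x$shear_axis[1], x$shear_axis[2]))
  invisible(x)
}

#' @rdname optical_config
#' @param optics An `optical_config`.
#' @export
object_pixel <- function(optics) optics$camera_pixel / optics$magnification

#' Point-spread-function scales of a diffraction-limited objective
#'
#' `psf_fwhm()` returns the full width at half maximum of the incoherent
#' Airy intensity PSF, `0.514 * lambda / NA`; `airy_radius()` returns the
#' first-zero (Rayleigh) radius `0.61 * lambda / NA`. Both in micrometers.
#'
#' @param wavelength Wavelength in micrometers.
#' @param na Numerical aperture.
#' @export
psf_fwhm <- function(wavelength, na) 0.514 * wavelength / na

#' @rdname psf_fwhm
#' @export
airy_radius <- function(wavelength, na) 0.61 * wavelength / na

# Airy intensity PSF [2 J1(v)/v]^2 sampled on the FFT grid of an ny x nx
# image (origin at [1,1]), normalized to unit sum so convolution conserves
# total intensity.
airy_intensity_kernel <- function(ny, nx, pixel_size, wavelength, na) {
  k <- 2 * pi * na / wavelength
  x <- fft_omega(nx) / (2 * pi) * nx * pixel_size  # signed pixel offsets * px
  y <- fft_omega(ny) / (2 * pi) * ny * pixel_size
  v <- k * sqrt(outer(y^2, x^2, `+`))
  a <- ifelse(v < 1e-8, 1, 2 * besselJ(v, 1) / v)
  psf <- a^2
  psf / sum(psf)
}

#' Retarder bias schedule for phase-shifting acquisition
#'
#' The ordered list of liquid-crystal retardance offsets `alpha_i` applied
#' between the e- and o-waves, one interferogram frame per bias, together
#' with the quadrature spacing weights `delta_i` used by the N-step
#' demodulator. The default is the uniform open schedule
#' `alpha_i = 2*pi*i/N, i = 0..N-1` with `delta_i = 2*pi/N`, covering one
#' full period.
#'
#' @param n Number of uniform bias levels (>= 3; >= 4 recommended). Ignored
#'   when `biases` is given.
#' @param biases Optional explicit bias values in radians.
#' @param deltas Optional spacing weights in radians; defaults to the
#'   uniform value `2*pi/length(biases)`.
#' @return An object of class `bias_schedule`.
#' @examples
#' bias_schedule(4)$biases  # 0, pi/2, pi, 3*pi/2
#' @export
bias_schedule <- function(n = 16, biases = NULL, deltas = NULL) {
  if (is.null(biases)) {
    n <- as.integer(n)
    if (n < 3) stop("bias_schedule: need at least 3 bias levels")
    biases <- 2 * pi * (0:(n - 1)) / n
    deltas <- rep(2 * pi / n, n)
  } else {
    if (length(biases) < 3) stop("bias_schedule: need at least 3 bias levels")
    if (is.null(deltas)) deltas <- rep(2 * pi / length(biases), length(biases))
    if (length(deltas) != length(biases))
      stop("bias_schedule: deltas must match biases in length")
  }
  structure(list(biases = as.numeric(biases), deltas = as.numeric(deltas)),
            class = "bias_schedule")
}

#' @export
print.bias_schedule <- function(x, ...) {
  cat(sprintf("<bias_schedule> %d levels: %s rad\n", length(x$biases),
              paste(signif(x$biases, 4), collapse = ", ")))
  invisible(x)
}

#' @export
length.bias_schedule <- function(x) length(x$biases)
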