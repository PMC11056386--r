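#' Specification of a spherical phantom particle
#'
#' Describes one dielectric sphere: its lateral center, diameter, and the
#' refractive indices of the particle and the surrounding immersion medium.
#' The optical phase delay of the sphere at lateral radius `rho` from its
#' center is `(2*pi/lambda) * (n_particle - n_medium) * t(rho)` with chord
#' length `t(rho) = 2 * sqrt((d/2)^2 - rho^2)`.
#'
#' Polystyrene calibration beads at 650 nm have `n_particle` close to 1.588
#' (dispersion places the index between the sodium-line 1.5894 and the
#' HeNe-line 1.587); typical immersion media are microscopy oil
#' (`n_medium = 1.518`) and water (`n_medium = 1.333`).
#'
#' @param center Numeric length-2, `(x, y)` center in micrometers.
#' @param diameter Sphere diameter in micrometers (> 0).
#' @param n_particle,n_medium Refractive indices, each in `[1, 2.5]`.
#' @return An object of class `sphere_spec`.
#' @examples
#' sphere_spec(c(5, 5), diameter = 1, n_particle = 1.588, n_medium = 1.518)
#' @export
sphere_spec <- function(center, diameter, n_particle, n_medium) {
  if (length(center) != 2 || !all(is.finite(center)))
    stop("sphere_spec: center must be finite (x, y) in micrometers")
  if (!is.finite(diameter) || diameter <= 0)
    stop("sphere_spec: diameter must be > 0")
  for (n in c(n_particle, n_medium))
    if (!is.finite(n) || n < 1 || n > 2.5)
      stop("sphere_spec: refractive indices must lie in [1, 2.5]")
  structure(list(center = as.numeric(center), diameter = diameter,
                 n_particle = n_particle, n_medium = n_medium),
            class = "sphere_spec")
}

#' @export
print.sphere_spec <- function(x, ...) {
  cat(sprintf("<sphere_spec> d = %g um at (%g, %g), n_p = %g, n_m = %g (dn = %+g)\n",
              x$diameter, x$center[1], x$center[2],
              x$n_particle, x$n_medium, x$n_particle - x$n_medium))
  invisible(x)
}

new_phase_phantom <- function(grid, phase, wavelength) {
  stopifnot_grid(grid)
  if (!all(is.finite(phase))) stop("phase_phantom: phase must be finite everywhere")
  structure(list(grid = grid, phase = phase, wavelength = wavelength),
            class = "phase_phantom")
}

#' @export
print.phase_phantom <- function(x, ...) {
  cat(sprintf("<phase_phantom> %d x %d px @ %.4g um, lambda = %g um, phase range [%.4g, %.4g] rad\n",
              x$grid$ny, x$grid$nx, x$grid$pixel_size, x$wavelength,
              min(x$phase), max(x$phase)))
  invisible(x)
}

#' Ground-truth phase map of spherical particles
#'
#' Evaluates, at each pixel center, the optical phase delay of a set of
#' dielectric spheres: `phase = (2*pi/wavelength) * dn * t` where `t` is the
#' chord length through the sphere at that lateral position. The peak of an
#' isolated sphere is therefore `(2*pi/wavelength) * dn * diameter` when a
#' pixel center coincides with the sphere center. Non-overlapping spheres
#' are additive; overlapping spheres are summed with a warning.
#'
#' @param grid An [image_grid()].
#' @param spheres A single [sphere_spec()] or a list of them.
#' @param wavelength Illumination wavelength in micrometers (> 0).
#' @return A `phase_phantom` whose `phase` matrix is zero outside every
#'   projected disc.
#' @examples
#' g <- image_grid(128, 128, 0.025)
#' ph <- make_sphere_phantom(g, sphere_spec(c(1.6, 1.6), 1, 1.588, 1.518), 0.65)
#' max(ph$phase)  # ~ 2*pi*0.070/0.65 = 0.68 rad
#' @export
make_sphere_phantom <- function(grid, spheres, wavelength) {
  stopifnot_grid(grid)
  if (!is.finite(wavelength) || wavelength <= 0)
    stop("make_sphere_phantom: wavelength must be > 0")
  if (inherits(spheres, "sphere_spec")) spheres <- list(spheres)
  if (!length(spheres)) stop("make_sphere_phantom: need at least one sphere")
  xy <- grid_xy(grid)
  xmax <- (grid$nx - 1) * grid$pixel_size
  ymax <- (grid$ny - 1) * grid$pixel_size
  phase <- matrix(0, grid$ny, grid$nx)
  support <- matrix(0L, grid$ny, grid$nx)
  for (sp in spheres) {
    if (!inherits(sp, "sphere_spec")) stop("spheres must be sphere_spec objects")
    r <- sp$diameter / 2
    if (sp$center[1] - r < 0 || sp$center[1] + r > xmax ||
        sp$center[2] - r < 0 || sp$center[2] + r > ymax)
      stop(sprintf(
        "make_sphere_phantom: sphere at (%g, %g) with diameter %g extends past the grid",
        sp$center[1], sp$center[2], sp$diameter))
    rho2 <- (xy$X - sp$center[1])^2 + (xy$Y - sp$center[2])^2
    inside <- rho2 < r^2
    chord <- ifelse(inside, 2 * sqrt(pmax(r^2 - rho2, 0)), 0)
    phase <- phase + (2 * pi / wavelength) * (sp$n_particle - sp$n_medium) * chord
    support <- support + as.integer(inside)
  }
  if (any(support > 1L))
    warning("make_sphere_phantom: overlapping spheres; phases were summed")
  new_phase_phantom(grid, phase, wavelength)
}

#' Constant (flat) phase phantom
#'
#' A null specimen: the same phase at every pixel. Used for background and
#' calibration tests, where the demodulated gradient must vanish.
#'
#' @inheritParams make_sphere_phantom
#' @param phase_value Constant phase in radians.
#' @param wavelength Wavelength in micrometers.
#' @return A `phase_phantom`.
#' @export
make_flat_phantom <- function(grid, phase_value = 0, wavelength = 0.65) {
  stopifnot_grid(grid)
  if (!is.finite(phase_value)) stop("make_flat_phantom: phase_value must be finite")
  new_phase_phantom(grid, matrix(phase_value, grid$ny, grid$nx), wavelength)
}

#' Band-limited random phase phantom
#'
#' A smooth, zero-mean Gaussian random field for round-trip property tests.
#' White noise is low-pass filtered with a Gaussian spectrum of 1/e^2
#' correlation length `correlation_length`, the mean is removed, and the
#' field is rescaled so that `max(abs(phase)) == amplitude`. The same seed
#' reproduces the same field bit for bit, and the session RNG state is left
#' untouched.
#'
#' @inheritParams make_flat_phantom
#' @param amplitude Maximum absolute phase in radians (>= 0).
#' @param correlation_length Spatial correlation scale in micrometers; must
#'   exceed `2 * pixel_size` so the field is resolved by the grid.
#' @param seed Integer seed.
#' @return A `phase_phantom`.
#' @export
make_random_phantom <- function(grid, amplitude, correlation_length, seed,
                                wavelength = 0.65) {
  stopifnot_grid(grid)
  if (!is.finite(amplitude) || amplitude < 0)
    stop("make_random_phantom: amplitude must be >= 0")
  if (correlation_length <= 2 * grid$pixel_size)
    stop("make_random_phantom: correlation_length must exceed 2 * pixel_size")
  if (amplitude == 0)
    return(new_phase_phantom(grid, matrix(0, grid$ny, grid$nx), wavelength))
  field <- with_private_seed(seed, {
    w <- matrix(stats::rnorm(grid$ny * grid$nx), grid$ny, grid$nx)
    kx <- fft_omega(grid$nx, grid$pixel_size)
    ky <- fft_omega(grid$ny, grid$pixel_size)
    k2 <- outer(ky^2, kx^2, `+`)
    filt <- exp(-k2 * correlation_length^2 / 8)  # 1/e^2 width = corr length
    Re(stats::fft(stats::fft(w) * filt, inverse = TRUE)) / length(w)
  })
  field <- field - mean(field)
  field <- field * (amplitude / max(abs(field)))
  new_phase_phantom(grid, field, wavelength)
}
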