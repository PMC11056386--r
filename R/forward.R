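new_interferogram <- function(grid, intensity, bias) {
  structure(list(grid = grid, intensity = intensity, bias = bias),
            class = "interferogram")
}

#' @export
print.interferogram <- function(x, ...) {
  cat(sprintf("<interferogram> %d x %d px, bias %.4g rad, intensity [%.4g, %.4g]\n",
              x$grid$ny, x$grid$nx, x$bias, min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' @export
print.interferogram_stack <- function(x, ...) {
  cat(sprintf("<interferogram_stack> %d frames, %d x %d px @ %.4g um\n",
              length(x$frames), x$grid$ny, x$grid$nx, x$grid$pixel_size))
  print(x$schedule)
  invisible(x)
}

#' Sheared e-/o-wave pair of a phase specimen
#'
#' Splits the specimen phase map into the two laterally sheared waves of a
#' DIC interferometer: the extraordinary wave samples the specimen at
#' `+s/2` along the shear axis and the ordinary wave at `-s/2`, so their
#' phase difference approximates `s * dPhi/dx` for smooth specimens. The
#' half-shears are applied by band-limited (Fourier) interpolation, which
#' handles sub-pixel shear distances exactly for band-limited fields.
#' Amplitudes default to 1 (pure phase specimen); an absorption map can be
#' supplied via `amplitude`.
#'
#' @param phantom A [make_sphere_phantom()]-style `phase_phantom`.
#' @param optics An [optical_config()] supplying `shear_distance` and
#'   `shear_axis`.
#' @param amplitude Optional common amplitude map (matrix) for both waves.
#' @return An object of class `wave_pair` with fields `amplitude_e`,
#'   `amplitude_o`, `phase_e`, `phase_o`, `grid`, `shear_axis`.
#' @export
shear_phase_pair <- function(phantom, optics, amplitude = NULL) {
  if (!inherits(phantom, "phase_phantom")) stop("expected a phase_phantom")
  if (!inherits(optics, "optical_config")) stop("expected an optical_config")
  u <- optics$shear_axis
  if (abs(sqrt(sum(u^2)) - 1) > 1e-9)
    stop("shear_phase_pair: shear axis must be unit-norm")
  px <- phantom$grid$pixel_size
  h <- optics$shear_distance / 2 / px  # half-shear in pixels
  phase_e <- fft_shift_image(phantom$phase, dx = +h * u[1], dy = +h * u[2])
  phase_o <- fft_shift_image(phantom$phase, dx = -h * u[1], dy = -h * u[2])
  if (is.null(amplitude)) amplitude <- matrix(1, phantom$grid$ny, phantom$grid$nx)
  if (any(amplitude < 0)) stop("shear_phase_pair: amplitudes must be >= 0")
  structure(list(amplitude_e = amplitude, amplitude_o = amplitude,
                 phase_e = phase_e, phase_o = phase_o,
                 grid = phantom$grid, shear_axis = u),
            class = "wave_pair")
}

#' DIC intensity at one retarder bias
#'
#' Two-beam interference of the sheared waves under a pre-specimen bias
#' `alpha`:
#' `I = J_o^2 + J_e^2 + 2 J_o J_e cos(theta_e - theta_o - alpha)`.
#' Intensities therefore lie in `[(J_e - J_o)^2, (J_e + J_o)^2]`.
#'
#' @param pair A [shear_phase_pair()] result.
#' @param bias Retarder bias `alpha` in radians.
#' @return An `interferogram`.
#' @export
interferogram <- function(pair, bias) {
  if (!inherits(pair, "wave_pair")) stop("expected a wave_pair")
  I <- pair$amplitude_o^2 + pair$amplitude_e^2 +
    2 * pair$amplitude_o * pair$amplitude_e *
      cos(pair$phase_e - pair$phase_o - bias)
  new_interferogram(pair$grid, I, bias)
}

#' Incoherent diffraction blur of an interferogram
#'
#' Convolves the intensity with the normalized 2-D Airy intensity PSF of the
#' objective (`[2 J1(v)/v]^2`, first zero at radius
#' `0.61 * wavelength / NA`). The kernel sums to one, so total intensity is
#' conserved. This is the fully incoherent blur model; the quasi-coherent
#' field-level alternative used by default in [acquire_bias_series()] is
#' discussed there.
#'
#' @param image An `interferogram`.
#' @param optics An [optical_config()].
#' @return The blurred `interferogram`.
#' @export
psf_blur <- function(image, optics) {
  if (!inherits(image, "interferogram")) stop("expected an interferogram")
  ker <- airy_intensity_kernel(image$grid$ny, image$grid$nx,
                               image$grid$pixel_size,
                               optics$wavelength, optics$na_objective)
  new_interferogram(image$grid, fft_convolve(image$intensity, ker), image$bias)
}

#' Poisson shot noise on a bias series
#'
#' Replaces every pixel of every frame by a Poisson draw with mean
#' `intensity * photons_per_unit`, rescaled back to intensity units. The
#' draw is seeded and reproducible, and the session RNG state is restored
#' afterwards.
#'
#' @param stack An `interferogram_stack`.
#' @param photons_per_unit Expected photon count per unit intensity (> 0).
#' @param seed Integer seed.
#' @return A noisy `interferogram_stack`.
#' @export
add_shot_noise <- function(stack, photons_per_unit, seed) {
  if (!inherits(stack, "interferogram_stack")) stop("expected an interferogram_stack")
  if (!is.finite(photons_per_unit) || photons_per_unit <= 0)
    stop("add_shot_noise: photons_per_unit must be > 0")
  frames <- with_private_seed(seed, {
    lapply(stack$frames, function(fr) {
      mu <- fr$intensity * photons_per_unit
      noisy <- matrix(stats::rpois(length(mu), lambda = mu), nrow(mu), ncol(mu))
      new_interferogram(fr$grid, noisy / photons_per_unit, fr$bias)
    })
  })
  stack$frames <- frames
  stack
}

#' Simulate a phase-shifted DIC bias series
#'
#' Produces one interferogram per bias level of the schedule. Three image
#' formation models are available:
#' \describe{
#'   \item{`"coherent"` (default)}{Quasi-coherent imaging: each sheared wave
#'     `J * exp(i * theta)` (the o-wave carrying the bias) is low-pass
#'     filtered by the objective pupil, and the two filtered fields
#'     interfere on the camera. The pupil edge is smoothed by the condenser
#'     source extent — the transfer is the normalized overlap area of the
#'     objective pupil disc (radius `NA_obj/lambda`) and the source disc
#'     (radius `NA_cond/lambda`), flat to `NA_obj - NA_cond` and rolling
#'     off to `NA_obj + NA_cond` — the leading-order partial-coherence
#'     correction for a Koehler system whose condenser NA is below the
#'     objective NA. Setting `na_condenser = 0` gives the ideal hard-edged
#'     coherent pupil.}
#'   \item{`"incoherent"`}{Eq.-of-interference intensity formed first, then
#'     blurred with the Airy intensity PSF via [psf_blur()].}
#'   \item{`"none"`}{No diffraction blur (ideal geometric imaging).}
#' }
#' Optional shot noise is applied per [add_shot_noise()]. Noiseless output
#' is independent of `seed`.
#'
#' @param phantom A `phase_phantom`.
#' @param optics An [optical_config()]; its pixel pitch must match the
#'   phantom grid within rounding, otherwise the phantom grid governs.
#' @param schedule A [bias_schedule()].
#' @param blur `"coherent"`, `"incoherent"`, or `"none"`.
#' @param photons_per_unit Optional Poisson photon budget per unit
#'   intensity; `NULL` for noiseless frames.
#' @param seed Integer seed for the noise (required when
#'   `photons_per_unit` is set).
#' @return An `interferogram_stack` with fields `frames`, `schedule`,
#'   `optics`, `grid`.
#' @examples
#' g <- image_grid(32, 32, 0.1)
#' st <- acquire_bias_series(make_flat_phantom(g), optical_config(),
#'                           bias_schedule(4), blur = "none")
#' sapply(st$frames, function(f) f$intensity[1, 1])  # 4, 2, 0, 2
#' @export
acquire_bias_series <- function(phantom, optics, schedule,
                                blur = c("coherent", "incoherent", "none"),
                                photons_per_unit = NULL, seed = NULL) {
  blur <- match.arg(blur)
  if (!inherits(schedule, "bias_schedule")) stop("expected a bias_schedule")
  if (!length(schedule$biases)) stop("acquire_bias_series: empty schedule")
  pair <- shear_phase_pair(phantom, optics)
  grid <- phantom$grid
  frames <- vector("list", length(schedule$biases))
  if (blur == "coherent") {
    ko <- 2 * pi * optics$na_objective / optics$wavelength
    kc <- 2 * pi * optics$na_condenser / optics$wavelength
    Ue <- pair$amplitude_e * exp(1i * pair$phase_e)
    Uo0 <- pair$amplitude_o * exp(1i * pair$phase_o)
    Ee <- fft_pupil_filter(Ue, grid$pixel_size, ko, kc)
    Eo0 <- fft_pupil_filter(Uo0, grid$pixel_size, ko, kc)
    for (i in seq_along(schedule$biases)) {
      a <- schedule$biases[i]
      # the bias is a global phase on the o-wave; it commutes with the pupil
      I <- Mod(Ee + Eo0 * exp(1i * a))^2
      frames[[i]] <- new_interferogram(grid, I, a)
    }
  } else {
    for (i in seq_along(schedule$biases)) {
      fr <- interferogram(pair, schedule$biases[i])
      if (blur == "incoherent") fr <- psf_blur(fr, optics)
      frames[[i]] <- fr
    }
  }
  stack <- structure(list(frames = frames, schedule = schedule,
                          optics = optics, grid = grid),
                     class = "interferogram_stack")
  if (!is.null(photons_per_unit)) {
    if (is.null(seed)) stop("acquire_bias_series: seed is required with shot noise")
    stack <- add_shot_noise(stack, photons_per_unit, seed)
  }
  stack
}

# intensity matrices of a stack as a list
stack_intensities <- function(stack) lapply(stack$frames, `[[`, "intensity")
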