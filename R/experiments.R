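# Packaged end-to-end calibration experiments: the peak-phase validation of
# a single bead and the replicate-averaged resolution (FWHM) measurement.
# Both run the full simulate -> demodulate -> integrate -> background-correct
# pipeline, so they exercise exactly what a user's reconstruction sees.

#' Full-pipeline peak-phase measurement of a calibration bead
#'
#' Simulates a phase-shifted bias series of a single bead, reconstructs the
#' quantitative phase image (N-step demodulation, Fourier integration,
#' rolling-ball background correction), and returns the robust peak phase.
#' The bead is centered on a pixel so the analytic peak
#' `(2 pi / lambda) dn d` is attainable; the robust peak averages over a
#' neighborhood of about half the PSF FWHM.
#'
#' @param optics An [optical_config()].
#' @param diameter Bead diameter in micrometers.
#' @param n_particle,n_medium Refractive indices of bead and medium.
#' @param nsteps Number of uniform bias levels.
#' @param grid_n Grid size in pixels (square).
#' @param photons_per_unit Shot-noise budget; `NULL` for noiseless.
#' @param seed Seed for the shot noise.
#' @param background_radius Rolling-ball radius in micrometers.
#' @return List with `peak` (robust peak, radians), `truth` (analytic
#'   peak), `phase` (the reconstructed `phase_image`), and `phantom`.
#' @export
bead_peak_experiment <- function(optics, diameter = 1.0, n_particle = 1.588,
                                 n_medium = 1.518, nsteps = 16, grid_n = 384,
                                 photons_per_unit = 1e4, seed = 1,
                                 background_radius = 5) {
  px <- object_pixel(optics)
  grid <- image_grid(grid_n, grid_n, px)
  c0 <- px * (grid_n %/% 2)  # on a pixel center
  phantom <- make_sphere_phantom(
    grid, sphere_spec(c(c0, c0), diameter, n_particle, n_medium),
    optics$wavelength)
  stack <- acquire_bias_series(phantom, optics, bias_schedule(nsteps),
                               blur = "coherent",
                               photons_per_unit = photons_per_unit,
                               seed = seed)
  grad <- demodulate_nstep(stack)
  rec <- integrate_hilbert(grad, optics$shear_distance)
  rec <- background_correct(rec, background_radius)
  k <- max(1L, floor(psf_fwhm(optics$wavelength, optics$na_objective) / 4 / px))
  list(peak = peak_phase(rec, k), truth = max(phantom$phase),
       phase = rec, phantom = phantom)
}

#' Replicate-averaged bead resolution (FWHM) measurement
#'
#' Emulates the standard planar-resolution measurement: `replicates`
#' identical beads are imaged independently through the full pipeline, each
#' at a random sub-pixel position (beads never sit exactly on a pixel
#' center in practice); the particle is re-detected in each reconstruction,
#' the along-shear traces through the detected (pixel-quantized) centers
#' are averaged on a common center-relative grid, and a Gaussian is fitted
#' to the average trace. The pixel quantization of the detected centers is
#' part of the procedure and contributes its registration jitter to the
#' measured width, exactly as in the bench measurement.
#'
#' @inheritParams bead_peak_experiment
#' @param replicates Number of independent beads (traces) to average.
#' @details The default photon budget is higher than for peak validation:
#'   resolution calibrations are acquired at high SNR so the fitted width,
#'   not the noise, limits the measurement.
#' @param half_window Trace half-length in micrometers; defaults to three
#'   Rayleigh radii.
#' @return A `profile_fit` (see [fwhm_gaussian_fit()]) with `n_particles =
#'   replicates`; the average trace is attached as attribute `"trace"`.
#' @export
bead_resolution_experiment <- function(optics, diameter, n_particle = 1.588,
                                       n_medium = 1.333, replicates = 20,
                                       nsteps = 16, grid_n = 128,
                                       photons_per_unit = 1e5, seed = 1,
                                       background_radius = 5,
                                       half_window = NULL) {
  px <- object_pixel(optics)
  grid <- image_grid(grid_n, grid_n, px)
  if (is.null(half_window))
    half_window <- 3 * airy_radius(optics$wavelength, optics$na_objective)
  c0 <- px * (grid_n %/% 2)
  offsets <- with_private_seed(seed, {
    matrix(stats::runif(2 * replicates, -px / 2, px / 2), ncol = 2)
  })
  traces <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    center <- c(c0 + offsets[r, 1], c0 + offsets[r, 2])
    phantom <- make_sphere_phantom(
      grid, sphere_spec(center, diameter, n_particle, n_medium),
      optics$wavelength)
    stack <- acquire_bias_series(phantom, optics, bias_schedule(nsteps),
                                 blur = "coherent",
                                 photons_per_unit = photons_per_unit,
                                 seed = seed + r)
    rec <- integrate_hilbert(demodulate_nstep(stack), optics$shear_distance)
    rec <- background_correct(rec, background_radius)
    det <- detect_particles(rec, 0.5,
                            min_separation = 3 * psf_fwhm(optics$wavelength,
                                                          optics$na_objective),
                            edge_margin = half_window)
    if (!nrow(det)) stop("bead_resolution_experiment: particle not detected")
    traces[[r]] <- average_particle_trace(rec, det[1, , drop = FALSE],
                                          half_window = half_window)
  }
  avg <- traces[[1]]
  if (replicates > 1)
    avg$value <- rowMeans(vapply(traces, `[[`, numeric(nrow(avg)), "value"))
  attr(avg, "n_particles") <- replicates
  fit <- fwhm_gaussian_fit(avg)
  fit$n_particles <- replicates
  attr(fit, "trace") <- avg
  fit
}
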