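# Shared fixtures, built in code at test time.

# Small optics for cheap pipeline tests: 0.1 um object pixel, shear 0.3 um.
test_optics <- function(shear = 0.3, na = 0.75, shear_axis = c(1, 0)) {
  optical_config(wavelength = 0.65, na_objective = na, na_condenser = 0.30,
                 magnification = 40, camera_pixel = 4,
                 shear_distance = shear, shear_axis = shear_axis)
}

test_grid <- function(n = 64, px = 0.1) image_grid(n, n, px)

# A wave pair with a prescribed constant phase difference, bypassing the
# phantom/shear machinery, for exact demodulation round trips.
constant_pair <- function(grid, dtheta) {
  structure(list(amplitude_e = matrix(1, grid$ny, grid$nx),
                 amplitude_o = matrix(1, grid$ny, grid$nx),
                 phase_e = matrix(dtheta, grid$ny, grid$nx),
                 phase_o = matrix(0, grid$ny, grid$nx),
                 grid = grid, shear_axis = c(1, 0)),
            class = "wave_pair")
}

# Stack of interferograms of a wave pair under a schedule (no blur/noise).
pair_stack <- function(pair, schedule, optics = test_optics(),
                       bias_offset = 0) {
  frames <- lapply(schedule$biases,
                   function(a) interferogram(pair, a + bias_offset))
  structure(list(frames = frames, schedule = schedule, optics = optics,
                 grid = pair$grid),
            class = "interferogram_stack")
}

# Gradient image built directly from a matrix (for integration tests).
gradient_from_matrix <- function(m, px = 0.1, shear_axis = c(1, 0)) {
  grom:::new_gradient_phase_image(image_grid(nrow(m), ncol(m), px), m,
                                  shear_axis, 16L)
}

phase_from_matrix <- function(m, px = 0.1, method = "hilbert") {
  grom:::new_phase_image(image_grid(nrow(m), ncol(m), px), m, method)
}

# Smooth random phantom with compact support: the band-limited field is
# apodized by a separable Hann window so the specimen vanishes at the
# borders, as a real field of view does.
apodized_random_phantom <- function(grid, amplitude, corr, seed) {
  ph <- make_random_phantom(grid, amplitude, corr, seed)
  hann <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  ph$phase <- ph$phase * outer(hann(grid$ny), hann(grid$nx))
  ph
}

# Analytic sheared difference of a phantom along x (the forward operator
# that integrate_hilbert inverts), via the package's band-limited shift.
sheared_difference <- function(phase, px, s) {
  grom:::fft_shift_image(phase, dx = +s / 2 / px) -
    grom:::fft_shift_image(phase, dx = -s / 2 / px)
}
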