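test_that("Fourier integration inverts the sheared difference of a sinusoid", {
  # Phi = A cos(k x'), with x' referenced to the mirror origin of the
  # integrator's even extension; the sheared difference is the closed form
  # -2 A sin(k s / 2) sin(k x'). Low frequency: k * s < 0.5.
  n <- 128; px <- 0.1; A <- 0.4
  L <- n * px
  k <- 3 * pi / L
  s <- 0.3
  stopifnot(k * s < 0.5)
  xp <- (0:(n - 1)) * px + px / 2
  truth <- matrix(rep(A * cos(k * xp), each = n), n, n)
  gmat <- matrix(rep(-2 * A * sin(k * s / 2) * sin(k * xp), each = n), n, n)
  rec <- integrate_hilbert(gradient_from_matrix(gmat, px), s)
  err <- rec$phase - truth
  err <- err - mean(err)  # DC is fixed to zero by convention
  expect_lt(sqrt(mean(err^2)) / A, 0.01)
})

test_that("zero gradient integrates to zero phase (c = 0 convention)", {
  z <- matrix(0, 32, 32)
  expect_true(all(integrate_hilbert(gradient_from_matrix(z), 0.3)$phase == 0))
  expect_true(all(integrate_cumulative(gradient_from_matrix(z), 0.3)$phase == 0))
  expect_true(all(wiener_deconvolve(gradient_from_matrix(z), 0.3)$phase == 0))
})

test_that("differentiate-then-integrate round trip is accurate for smooth fields", {
  g <- test_grid(96, 0.1)
  ph <- apodized_random_phantom(g, 0.5, 1.2, seed = 5)
  s <- 0.3
  gmat <- sheared_difference(ph$phase, 0.1, s)
  rec <- integrate_hilbert(gradient_from_matrix(gmat, 0.1), s)
  err <- rec$phase - ph$phase
  err <- err - mean(err)
  expect_lt(sqrt(mean(err^2)) / stats::sd(ph$phase), 0.02)
})

test_that("integration is linear and insensitive to the unobservable constant", {
  g <- image_grid(96, 96, 0.05)
  s <- 0.2
  p1 <- make_sphere_phantom(g, sphere_spec(c(1.5, 1.5), 1, 1.588, 1.518), 0.65)
  p2 <- make_sphere_phantom(g, sphere_spec(c(3.3, 3.3), 1, 1.588, 1.518), 0.65)
  g1 <- sheared_difference(p1$phase, 0.05, s)
  g2 <- sheared_difference(p2$phase, 0.05, s)
  r_sum <- integrate_hilbert(gradient_from_matrix(g1 + g2, 0.05), s)
  r_sep <- integrate_hilbert(gradient_from_matrix(g1, 0.05), s)$phase +
    integrate_hilbert(gradient_from_matrix(g2, 0.05), s)$phase
  expect_lt(max(abs(r_sum$phase - r_sep)), 1e-6)
  # adding a constant to the true phase leaves the reconstruction unchanged
  gc <- sheared_difference(p1$phase + 0.7, 0.05, s)
  expect_lt(max(abs(gc - g1)), 1e-9)
})

test_that("cumulative integration matches the antiderivative of a ramp gradient", {
  n <- 64; px <- 0.1; s <- 0.25; a <- 0.02
  x <- (0:(n - 1)) * px
  gmat <- matrix(rep(a * x, each = n), n, n)  # gradient rises linearly in x
  rec <- integrate_cumulative(gradient_from_matrix(gmat, px), s)
  # rectangle-rule antiderivative of a*x/s, anchored at x = 0
  truth <- (cumsum(a * x) - a * x[1]) * px / s
  truth <- truth - truth[1]
  expect_equal(rec$phase[10, ], truth, tolerance = 1e-9)
  # discretization error against the continuous antiderivative a x^2 / (2 s)
  cont <- a * x^2 / (2 * s)
  expect_lt(max(abs(rec$phase[10, ] - cont)), a * px * max(x) / s)
})

test_that("cumulative integration of white noise random-walks along x", {
  set.seed(13)
  n <- 4000; nx <- 256; px <- 0.1; s <- 0.25; sg <- 0.05
  gmat <- matrix(stats::rnorm(n * nx, sd = sg), n, nx)
  rec <- integrate_cumulative(gradient_from_matrix(gmat, px), s)
  v <- apply(rec$phase, 2, stats::var)
  # var(Phi at column j) = (j - 1) * sg^2 * (px/s)^2 (first column anchored)
  for (j in c(65, 129, 255)) {
    expect_equal(v[j], (j - 1) * sg^2 * (px / s)^2, tolerance = 0.15)
  }
})

test_that("Wiener deconvolution agrees with Fourier integration at high SNR", {
  g <- test_grid(96, 0.1)
  ph <- apodized_random_phantom(g, 0.5, 1.2, seed = 7)
  s <- 0.3
  gmat <- sheared_difference(ph$phase, 0.1, s)
  grad <- gradient_from_matrix(gmat, 0.1)
  rh <- integrate_hilbert(grad, s)$phase
  rw <- wiener_deconvolve(grad, s, snr_parameter = 1e8)$phase
  d <- rh - rw
  expect_lt(sqrt(mean(d^2)) / stats::sd(rh), 0.02)
  expect_error(wiener_deconvolve(grad, s, snr_parameter = -1), "snr")
})

test_that("Fourier integration preserves the bead peak better than Wiener", {
  # the regularized inverse trades variance for a low-frequency bias that
  # depresses the bead's phase amplitude; the exact inversion is unbiased.
  # Peak amplitude fidelity is the standard bead-validation metric.
  opt <- optical_config(0.65, 0.75, 0.30, magnification = 40, camera_pixel = 4)
  px <- object_pixel(opt)
  n <- 128
  g <- image_grid(n, n, px)
  c0 <- px * (n / 2)
  ph <- make_sphere_phantom(g, sphere_spec(c(c0, c0), 1, 1.588, 1.518), 0.65)
  truth_pk <- peak_phase(ph$phase, 1)
  for (seed in c(5, 21)) {
    st <- acquire_bias_series(ph, opt, bias_schedule(16), blur = "coherent",
                              photons_per_unit = 100, seed = seed)
    grad <- demodulate_nstep(st)
    h <- background_correct(integrate_hilbert(grad, opt$shear_distance), 5)
    w <- background_correct(wiener_deconvolve(grad, opt$shear_distance, 100), 5)
    expect_lt(abs(peak_phase(h, 1) - truth_pk),
              abs(peak_phase(w, 1) - truth_pk))
  }
})

test_that("rolling-ball background correction removes offsets and ramps", {
  flat <- phase_from_matrix(matrix(0.37, 48, 48))
  out <- background_correct(flat, 1)
  expect_lt(max(abs(out$phase)), 1e-12)
  # bead riding on a linear ramp: peak height preserved within 3%
  g <- image_grid(128, 128, 0.05)
  c0 <- 0.05 * 64
  bead <- make_sphere_phantom(g, sphere_spec(c(c0, c0), 1, 1.588, 1.518), 0.65)
  ramp <- matrix(rep(seq(0, 0.5, length.out = 128), each = 128), 128, 128)
  img <- phase_from_matrix(bead$phase + ramp, 0.05)
  corr <- background_correct(img, 8)  # radius well above the bead size
  expect_equal(peak_phase(corr, 1), peak_phase(bead$phase, 1), tolerance = 0.03)
  # residual background is flat near zero away from the bead
  border <- corr$phase[10:20, 40:90]
  expect_lt(mean(abs(border)), 1e-2)
})

test_that("background correction is idempotent", {
  g <- image_grid(96, 96, 0.05)
  c0 <- 0.05 * 48
  bead <- make_sphere_phantom(g, sphere_spec(c(c0, c0), 1, 1.588, 1.518), 0.65)
  set.seed(3)
  img <- phase_from_matrix(bead$phase + 0.2 +
                             matrix(rnorm(96^2, sd = 0.005), 96, 96), 0.05)
  depth <- diff(range(img$phase))
  once <- background_correct(img, 8, depth = depth)
  twice <- background_correct(once, 8, depth = depth)
  expect_lt(sqrt(mean((twice$phase - once$phase)^2)), 1e-3)
  expect_error(background_correct(img, 0.05), "radius")
})

test_that("z-stacks reconstruct plane by plane, order-independently", {
  g <- test_grid(32, 0.1)
  opt <- test_optics(shear = 0.2)
  stacks <- lapply(1:12, function(z) {
    ph <- make_random_phantom(g, 0.2 + 0.01 * z, 0.5, seed = z)
    acquire_bias_series(ph, opt, bias_schedule(4), blur = "none")
  })
  vol <- reconstruct_volume(stacks, method = "hilbert")
  expect_length(vol, 12)
  # single plane reduces to the 2-D pipeline
  single <- reconstruct_volume(stacks[1])[[1]]
  direct <- integrate_hilbert(demodulate_nstep(stacks[[1]]), 0.2)
  expect_equal(single$phase, direct$phase, tolerance = 1e-12)
  # permute and unpermute
  perm <- sample(12)
  vol_p <- reconstruct_volume(stacks[perm])
  expect_equal(vol_p[[which(perm == 5)]]$phase, vol[[5]]$phase,
               tolerance = 1e-12)
  # inconsistent grids are rejected
  bad <- stacks
  bad[[2]]$grid <- image_grid(32, 32, 0.2)
  expect_error(reconstruct_volume(bad), "grids")
})

test_that("phase converts to refractive-index difference", {
  p <- phase_from_matrix(matrix(0.68, 16, 16))
  dn <- phase_to_index(p, wavelength = 0.65, thickness = 1)
  expect_equal(dn[1, 1], 0.68 * 0.65 / (2 * pi), tolerance = 1e-12)
  expect_error(phase_to_index(p, 0.65, 0), "thickness")
})
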