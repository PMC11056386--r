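test_that("peak phase of an analytic bead matches the chord formula", {
  g <- image_grid(96, 96, 0.025)
  c0 <- 0.025 * 48
  ph <- make_sphere_phantom(g, sphere_spec(c(c0, c0), 1, 1.588, 1.518), 0.65)
  pk <- peak_phase(phase_from_matrix(ph$phase, 0.025), 1)
  expect_equal(pk, 2 * pi / 0.65 * 0.070, tolerance = 0.01)
  expect_equal(peak_phase(phase_from_matrix(matrix(0, 16, 16))), 0)
})

test_that("robust peak averages down single-pixel spikes", {
  m <- matrix(0, 32, 32)
  m[16, 16] <- 9
  expect_equal(peak_phase(m, 0), 9)
  expect_equal(peak_phase(m, 1), 1, tolerance = 1e-12)  # 9 / 9 neighborhood
})

test_that("Gaussian fit recovers the closed-form FWHM", {
  x <- seq(-6, 6, by = 0.02)
  prof <- data.frame(position = x, value = 1.3 * exp(-x^2 / 2) + 0.05)
  fit <- fwhm_gaussian_fit(prof)
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)), tolerance = 1e-6)
  expect_equal(fit$amplitude, 1.3, tolerance = 1e-6)
  expect_equal(fit$offset, 0.05, tolerance = 1e-6)
})

test_that("FWHM estimator is unbiased across widths", {
  px <- 1  # positions in pixels
  for (sigma in c(2, 10, 50)) {
    x <- seq(-6 * sigma, 6 * sigma, by = px)
    fit <- fwhm_gaussian_fit(data.frame(position = x,
                                        value = exp(-x^2 / (2 * sigma^2))))
    expect_equal(fit$fwhm, 2.354820045 * sigma, tolerance = 1e-6)
  }
})

test_that("FWHM of convolved Gaussians adds in quadrature", {
  # oracle for resolution-versus-particle-size accounting
  dx <- 0.01
  x <- seq(-10, 10, by = dx)
  s1 <- 0.8; s2 <- 1.7
  g1 <- exp(-x^2 / (2 * s1^2)); g2 <- exp(-x^2 / (2 * s2^2))
  conv <- stats::convolve(g1, rev(g2), type = "open") * dx
  xc <- seq(-20, 20, by = dx)[seq_along(conv)]
  fit <- fwhm_gaussian_fit(data.frame(position = xc, value = conv))
  f1 <- 2.354820045 * s1; f2 <- 2.354820045 * s2
  expect_equal(fit$fwhm, sqrt(f1^2 + f2^2), tolerance = 1e-3)
})

test_that("Gaussian fit of a top-hat matches a brute-force least-squares fit", {
  x <- seq(-5, 5, by = 0.01)
  w <- 2.4
  y <- as.numeric(abs(x) <= w / 2)
  fit <- fwhm_gaussian_fit(data.frame(position = x, value = y))
  # independent oracle: direct minimization from several starts
  sse <- function(p) sum((y - (p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4]))^2)
  best <- Inf
  for (sg0 in c(0.5, 1, 2)) {
    o <- stats::optim(c(1, 0, sg0, 0), sse, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    if (o$value < best) { best <- o$value; opt <- o$par }
  }
  expect_equal(fit$fwhm, 2.354820045 * abs(opt[3]), tolerance = 1e-3)
  # sanity: the fitted width tracks the top-hat scale
  expect_gt(fit$fwhm, 0.7 * w)
  expect_lt(fit$fwhm, 1.25 * w)
})

test_that("fit standard error shrinks like 1 / sqrt(n traces)", {
  x <- seq(-5, 5, by = 0.1)
  clean <- exp(-x^2 / 2)
  ses <- sapply(c(5, 20, 80), function(n) {
    set.seed(100 + n)
    noisy <- replicate(n, clean + rnorm(length(x), sd = 0.2))
    fit <- fwhm_gaussian_fit(data.frame(position = x, value = rowMeans(noisy)))
    fit$fwhm_se
  })
  expect_true(ses[1] > ses[2] && ses[2] > ses[3])
  expect_equal(ses[1] / ses[3], sqrt(80 / 5), tolerance = 0.35)
})

test_that("non-fittable profiles raise a residual-carrying error", {
  x <- seq(0, 1, by = 0.1)
  expect_error(fwhm_gaussian_fit(data.frame(position = x[1:3], value = x[1:3])),
               "too short")
})

test_that("particle detection finds isolated beads and respects separation", {
  g <- image_grid(128, 128, 0.05)
  centers <- list(c(1.5, 1.5), c(4.5, 1.5), c(3, 4.5))
  spheres <- lapply(centers, function(cc) sphere_spec(cc, 1, 1.588, 1.518))
  ph <- make_sphere_phantom(g, spheres, 0.65)
  det <- detect_particles(phase_from_matrix(ph$phase, 0.05), 0.5,
                          min_separation = 1.0)
  expect_equal(nrow(det), 3)
  found <- det[order(det$x, det$y), ]
  want <- do.call(rbind, centers)[order(sapply(centers, `[`, 1)), ]
  expect_equal(found$x, want[, 1], tolerance = 0.06)
  expect_equal(found$y, want[, 2], tolerance = 0.06)
  # a huge separation collapses detections to the single strongest
  det1 <- detect_particles(phase_from_matrix(ph$phase, 0.05), 0.5,
                           min_separation = 10)
  expect_equal(nrow(det1), 1)
  # featureless image yields no detections
  expect_equal(nrow(detect_particles(phase_from_matrix(matrix(1, 32, 32)),
                                     0.5, 1)), 0)
})

test_that("trace averaging equals a single trace for identical noiseless beads", {
  g <- image_grid(256, 64, 0.05)
  centers <- lapply(1:10, function(i) c(1.6, 0.05 * (16 + 24 * (i - 1))))
  spheres <- lapply(centers, function(cc) sphere_spec(cc, 1, 1.588, 1.518))
  ph <- make_sphere_phantom(g, spheres, 0.65)
  img <- phase_from_matrix(ph$phase, 0.05)
  det <- data.frame(x = sapply(centers, `[`, 1), y = sapply(centers, `[`, 2))
  avg <- average_particle_trace(img, det, half_window = 0.5)
  expect_equal(attr(avg, "n_particles"), 10)
  single <- average_particle_trace(img, det[1, , drop = FALSE], half_window = 0.5)
  expect_equal(avg$value, single$value, tolerance = 1e-12)
})

test_that("trace averaging suppresses noise by ~ the number of traces", {
  g <- image_grid(512, 64, 0.05)
  centers <- lapply(1:20, function(i) c(1.6, 0.05 * (16 + 24 * (i - 1))))
  spheres <- lapply(centers, function(cc) sphere_spec(cc, 1, 1.588, 1.518))
  clean <- make_sphere_phantom(g, spheres, 0.65)$phase
  set.seed(9)
  noisy <- phase_from_matrix(clean + matrix(rnorm(512 * 64, sd = 0.05), 512, 64),
                             0.05)
  det <- data.frame(x = sapply(centers, `[`, 1), y = sapply(centers, `[`, 2))
  avg <- average_particle_trace(noisy, det, half_window = 0.5)
  ref <- average_particle_trace(phase_from_matrix(clean, 0.05),
                                det[1, , drop = FALSE], half_window = 0.5)
  resid_var <- stats::var(avg$value - ref$value)
  expect_gt(0.05^2 / resid_var, 12)
  expect_lt(0.05^2 / resid_var, 33)
})

test_that("edge-adjacent detections are skipped with a warning; empty input errors", {
  img <- phase_from_matrix(matrix(0, 64, 64), 0.1)
  img$phase[32, 3] <- 1
  det <- data.frame(x = 0.2, y = 3.1)
  expect_warning(expect_error(
    average_particle_trace(img, det, half_window = 1),
    "no usable"), "skipped")
  expect_error(average_particle_trace(img, det[0, ], half_window = 1), "empty")
})

test_that("line profile is constant on constant images and peaks with the bead", {
  img <- phase_from_matrix(matrix(0.25, 64, 64), 0.1)
  prof <- radial_profile(img, from = c(0.5, 3.2), to = c(5.5, 3.2), width = 0.6)
  expect_true(all(abs(prof$value - 0.25) < 1e-12))
  g <- image_grid(128, 128, 0.05)
  c0 <- 0.05 * 64
  bead <- make_sphere_phantom(g, sphere_spec(c(c0, c0), 1, 1.588, 1.518), 0.65)
  bimg <- phase_from_matrix(bead$phase, 0.05)
  bp <- radial_profile(bimg, from = c(0.5, c0), to = c(5.9, c0), width = 0.1)
  expect_equal(max(bp$value), peak_phase(bimg, 1), tolerance = 0.02)
  expect_error(radial_profile(bimg, c(-1, 0), c(2, 2), 0.5), "outside")
})

test_that("an elongated phantom with rising density yields a rising profile", {
  # synthetic root-like specimen: density (and phase) grows toward the tip
  n <- 96; px <- 0.1
  x <- (0:(n - 1)) * px; y <- x
  body <- outer(exp(-(y - 4.8)^2 / 2), rep(1, n))      # tube along x
  dens <- matrix(rep(seq(0.2, 1, length.out = n), each = n), n, n)
  img <- phase_from_matrix(body * dens, px)
  prof <- radial_profile(img, from = c(0.5, 4.8), to = c(9, 4.8), width = 2)
  fit <- stats::lm(prof$value ~ prof$position)
  expect_gt(stats::coef(fit)[2], 0)
  expect_gt(stats::cor(prof$position, prof$value), 0.95)
})
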