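new_phase_image <- function(grid, phase, method, background_constant = 0) {
  structure(list(grid = grid, phase = phase,
                 background_constant = background_constant, method = method),
            class = "phase_image")
}

#' @export
print.phase_image <- function(x, ...) {
  cat(sprintf("<phase_image> %d x %d px @ %.4g um, method '%s', range [%.4g, %.4g] rad\n",
              x$grid$ny, x$grid$nx, x$grid$pixel_size, x$method,
              min(x$phase), max(x$phase)))
  invisible(x)
}

# Orient the gradient so the shear axis runs along matrix columns, apply a
# row-wise operation, and restore the original orientation.
with_shear_rows <- function(grad, fun) {
  u <- grad$shear_axis
  along_x <- abs(abs(u[1]) - 1) < 1e-9
  along_y <- abs(abs(u[2]) - 1) < 1e-9
  if (!along_x && !along_y)
    stop("only axis-aligned shear vectors (1,0) / (0,1) are supported here")
  g <- grad$grad_phase
  if (along_y) g <- t(g)
  sgn <- if (along_x) sign(u[1]) else sign(u[2])
  out <- fun(g * sgn)
  if (along_y) out <- t(out)
  out
}

# Row-wise Fourier inversion of the shear-difference operator. Rows are
# extended antisymmetrically (odd extension) to twice their length before
# the FFT: the gradient is derivative-like, so its odd extension corresponds
# to an even (mirror) extension of the phase and suppresses wrap-around
# edge artifacts. `filter_fun(H)` maps the forward transfer H(k) = 2i *
# sin(k s / 2) to the inverse actually applied.
invert_gradient_rows <- function(grad, shear_distance, filter_fun) {
  px <- grad$grid$pixel_size
  with_shear_rows(grad, function(g) {
    nx <- ncol(g); n2 <- 2L * nx
    k <- fft_omega(n2, px)
    H <- 2i * sin(k * shear_distance / 2)
    inv <- filter_fun(H, k)
    ext <- cbind(g, -g[, nx:1, drop = FALSE])
    out <- t(apply(ext, 1, function(row)
      Re(stats::fft(stats::fft(row) * inv, inverse = TRUE)) / n2))
    out <- out[, seq_len(nx), drop = FALSE]
    sweep(out, 1, out[, 1])   # c = Phi(0, y) = 0 anchors each row's origin
  })
}

#' Quantitative phase by Fourier (Hilbert-kernel) integration
#'
#' Inverts the shear-difference operator row by row along the shear axis:
#' the spectrum of each (mirror-extended) row is divided by the forward
#' transfer function `H(k) = 2i sin(k s / 2)` of a finite-difference over
#' the shear distance `s`, with the `k = 0` component set to zero. Zeroing
#' the DC term fixes the integration constant `c` of the line integral to
#' zero, i.e. no wavefront distortion at the row origin; the arbitrary
#' constant of the true phase is not recoverable from its gradient. For
#' small `k * s` the filter reduces to `1 / (i k s)`, the classic
#' Hilbert-kernel (signum) integration filter.
#'
#' When the shear spans more than two pixels, `H` also vanishes at the
#' in-band frequencies `k = 2 pi m / s` (`m >= 1`). Those components are
#' annihilated by the finite-difference acquisition — they are
#' unobservable — so the filter zeroes a narrow notch
#' (`|k s / 2 - m pi| < 0.05`) around them instead of amplifying noise
#' there without bound. The exact inverse is kept everywhere else, in
#' particular at all low frequencies.
#'
#' @param grad A `gradient_phase_image` (radians per shear).
#' @param shear_distance Shear distance `s` in micrometers (> 0); defaults
#'   to the value implied by the acquisition when the gradient was produced
#'   through [grom_reconstruct()], otherwise it must be given.
#' @return A `phase_image` (method `"hilbert"`) in radians.
#' @export
integrate_hilbert <- function(grad, shear_distance) {
  if (!inherits(grad, "gradient_phase_image")) stop("expected a gradient_phase_image")
  if (!is.finite(shear_distance) || shear_distance <= 0)
    stop("integrate_hilbert: shear_distance must be > 0")
  phase <- invert_gradient_rows(grad, shear_distance, function(H, k) {
    m <- round(k * shear_distance / (2 * pi))
    # DC fixes c = 0; narrow notches around the aliased zeros (m >= 1) cap
    # the gain at 1/0.05 there. The m = 0 low-frequency branch keeps the
    # exact inverse: its growing gain is inherent to gradient integration.
    dead <- (k == 0) | (m != 0 & Mod(H) < 0.05)
    ifelse(dead, 0 + 0i, 1 / H)
  })
  new_phase_image(grad$grid, phase, "hilbert")
}

#' Quantitative phase by cumulative summation
#'
#' The literal running-sum reading of the line-integral relation: the
#' gradient (a finite difference over the shear distance `s`) is scaled by
#' `pixel_size / s` and cumulatively summed along each row, with the first
#' column anchored at zero. Kept as a didactic baseline: under noise the
#' row sums random-walk, producing the characteristic horizontal streaks.
#'
#' @inheritParams integrate_hilbert
#' @return A `phase_image` (method `"cumulative"`).
#' @export
integrate_cumulative <- function(grad, shear_distance) {
  if (!inherits(grad, "gradient_phase_image")) stop("expected a gradient_phase_image")
  if (!is.finite(shear_distance) || shear_distance <= 0)
    stop("integrate_cumulative: shear_distance must be > 0")
  px <- grad$grid$pixel_size
  phase <- with_shear_rows(grad, function(g) {
    out <- t(apply(g, 1, cumsum)) * (px / shear_distance)
    sweep(out, 1, out[, 1])  # c = Phi(0, y) = 0
  })
  new_phase_image(grad$grid, phase, "cumulative")
}

#' Quantitative phase by Wiener deconvolution
#'
#' Regularized inverse filtering of the shear-difference transfer function,
#' applied row-wise with the same mirror extension as
#' [integrate_hilbert()]:
#' `Phi_hat = Conj(H) G / (|H|^2 + 1/snr)` with `H(k) = 2i sin(k s / 2)`.
#' At high `snr` and moderate `k s` this agrees with the Fourier
#' integration; under noise the flat-spectrum regularization is the
#' historical baseline that direct gradient-to-phase deconvolution methods
#' used, and it is retained for comparison.
#'
#' @inheritParams integrate_hilbert
#' @param snr_parameter Signal-to-noise regularization parameter (> 0).
#' @return A `phase_image` (method `"wiener"`).
#' @export
wiener_deconvolve <- function(grad, shear_distance, snr_parameter = 100) {
  if (!inherits(grad, "gradient_phase_image")) stop("expected a gradient_phase_image")
  if (!is.finite(snr_parameter) || snr_parameter <= 0)
    stop("wiener_deconvolve: snr_parameter must be > 0")
  if (!is.finite(shear_distance) || shear_distance <= 0)
    stop("wiener_deconvolve: shear_distance must be > 0")
  phase <- invert_gradient_rows(grad, shear_distance, function(H, k) {
    Conj(H) / (Mod(H)^2 + 1 / snr_parameter)
  })
  new_phase_image(grad$grid, phase, "wiener")
}

# 1-D grayscale erosion (op = pmin) or dilation (op = pmax) of the matrix
# columns-axis with a parabolic structuring profile p(d) = curv * d^2,
# implemented as a vectorized shift-and-compare loop. Border pixels see a
# shrinking window (+/- Inf padding).
parabolic_pass <- function(m, curv, W, dilate = FALSE) {
  n <- ncol(m)
  out <- m
  pad <- if (dilate) -Inf else Inf
  for (d in seq_len(W)) {
    p <- curv * d^2
    right <- cbind(m[, -seq_len(d), drop = FALSE],
                   matrix(pad, nrow(m), d))
    left <- cbind(matrix(pad, nrow(m), d),
                  m[, seq_len(n - d), drop = FALSE])
    if (dilate) {
      out <- pmax(out, right - p, left - p)
    } else {
      out <- pmin(out, right + p, left + p)
    }
  }
  out
}

#' Rolling-ball background correction
#'
#' Subtracts a morphological background estimate: a grayscale opening with
#' a sliding-paraboloid structuring element (the standard smooth variant of
#' the rolling-ball operator). The paraboloid has lateral radius `radius`
#' micrometers and a depth equal to the image dynamic range, so structures
#' narrower than the radius (particles, cells) ride on top of the estimated
#' background and survive the subtraction, while offsets and slow ramps are
#' removed. Opening is idempotent, so a second pass changes almost nothing.
#'
#' Two standard refinements keep the estimate unbiased under noise: the
#' ball rolls on a 3 x 3 box-smoothed copy of the image (so it does not
#' hug single-pixel noise minima), and the subtracted background is
#' recentred so the median of the corrected image is zero — an opening is a
#' lower envelope and would otherwise shift a noisy background up by the
#' noise envelope depth. Recentring assumes specimens are sparse (the
#' median pixel is background), which holds for calibration phantoms.
#'
#' `radius` must comfortably exceed the largest specimen feature; a good
#' default is tens of PSF widths.
#'
#' @param phase A `phase_image`.
#' @param radius Ball radius in micrometers (>= 2 pixels). The paraboloid
#'   lifts by `depth * (w / radius)^2` when bridging a feature of half-width
#'   `w`, so choose `radius` several times the largest feature to keep peak
#'   heights intact.
#' @param depth Height of the structuring paraboloid at lateral distance
#'   `radius`, in radians; defaults to the image dynamic range. Pass it
#'   explicitly to reuse the identical structuring element across calls
#'   (exact opening idempotence).
#' @return The corrected `phase_image`; the subtracted background's mean is
#'   recorded in `background_constant`.
#' @export
background_correct <- function(phase, radius, depth = NULL) {
  if (!inherits(phase, "phase_image")) stop("expected a phase_image")
  px <- phase$grid$pixel_size
  if (!is.finite(radius) || radius < 2 * px)
    stop("background_correct: radius must be at least 2 pixels")
  f <- phase$phase
  H <- depth %||% diff(range(f))
  if (H == 0) {
    out <- new_phase_image(phase$grid, f - f[1, 1], phase$method, f[1, 1])
    return(out)
  }
  curv <- H / radius^2 * px^2        # parabola depth H at lateral distance R
  W <- min(ceiling(radius * sqrt(2) / px), max(dim(f)) - 1L)
  fs <- box_mean(f, 1)               # roll the ball on the smoothed image
  er <- parabolic_pass(t(parabolic_pass(fs, curv, W)), curv, W)       # nx x ny
  bg <- parabolic_pass(t(parabolic_pass(er, curv, W, dilate = TRUE)),
                       curv, W, dilate = TRUE)                        # ny x nx
  bg <- bg + stats::median(f - bg)   # opening is a lower envelope; recentre
  new_phase_image(phase$grid, f - bg, phase$method, mean(bg))
}

#' Plane-by-plane reconstruction of a z-stack
#'
#' Applies the demodulate-integrate(-correct) pipeline independently to
#' each z-plane of a focal series. Planes are treated as uncoupled 2-D
#' acquisitions; no axial deconvolution is attempted.
#'
#' @param stacks List of `interferogram_stack` objects, one per z-plane,
#'   sharing one grid.
#' @param method `"hilbert"`, `"cumulative"`, or `"wiener"`.
#' @param demodulation `"nstep"` or `"4step"`.
#' @param background_radius Optional rolling-ball radius in micrometers;
#'   `NULL` skips the correction.
#' @param snr_parameter Passed to [wiener_deconvolve()] when used.
#' @return A list of `phase_image` objects in input order.
#' @export
reconstruct_volume <- function(stacks, method = "hilbert",
                               demodulation = c("nstep", "4step"),
                               background_radius = NULL,
                               snr_parameter = 100) {
  demodulation <- match.arg(demodulation)
  if (!length(stacks)) stop("reconstruct_volume: empty stack list")
  g0 <- stacks[[1]]$grid
  for (st in stacks) {
    if (!inherits(st, "interferogram_stack"))
      stop("reconstruct_volume: expected interferogram_stack objects")
    if (!same_grid(st$grid, g0))
      stop("reconstruct_volume: inconsistent grids across planes")
  }
  lapply(stacks, function(st) {
    grad <- if (demodulation == "4step") demodulate_4step(st)
            else demodulate_nstep(st)
    s <- st$optics$shear_distance
    ph <- switch(method,
                 hilbert = integrate_hilbert(grad, s),
                 cumulative = integrate_cumulative(grad, s),
                 wiener = wiener_deconvolve(grad, s, snr_parameter),
                 stop("reconstruct_volume: unknown method '", method, "'"))
    if (!is.null(background_radius)) ph <- background_correct(ph, background_radius)
    ph
  })
}

#' Convert a phase image to refractive-index difference
#'
#' For a specimen of known thickness `t`, `dn = dPhi * lambda / (2 * pi *
#' t)` converts the measured phase delay to the refractive-index contrast
#' against the surrounding medium.
#'
#' @param phase A `phase_image`.
#' @param wavelength Wavelength in micrometers.
#' @param thickness Specimen thickness in micrometers.
#' @return A matrix of index differences.
#' @export
phase_to_index <- function(phase, wavelength, thickness) {
  if (thickness <= 0) stop("phase_to_index: thickness must be > 0")
  phase$phase * wavelength / (2 * pi * thickness)
}
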