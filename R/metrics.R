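#' Robust peak phase of a reconstructed image
#'
#' The maximum of the box-filtered image: each pixel is replaced by the
#' mean over a `(2k+1) x (2k+1)` neighborhood (borders use the shrinking
#' window) and the maximum of that local mean is returned. Averaging over a
#' small neighborhood makes the peak estimate robust against single-pixel
#' noise while leaving a noiseless peak essentially unchanged.
#'
#' @param phase A `phase_image` (or plain matrix).
#' @param neighborhood Half-width `k` of the averaging window in pixels
#'   (default 1, i.e. 3 x 3).
#' @return Peak phase in radians.
#' @export
peak_phase <- function(phase, neighborhood = 1) {
  m <- if (inherits(phase, "phase_image")) phase$phase else phase
  k <- as.integer(neighborhood)
  if (k < 0) stop("peak_phase: neighborhood must be >= 0")
  if (k > 0) m <- box_mean(m, k)
  max(m)
}

# shrinking-window box mean, separable running sums
box_mean <- function(m, k) {
  sm_x <- t(apply(m, 1, running_mean, k))  # smooth along x (columns)
  apply(sm_x, 2, running_mean, k)          # then along y, orientation kept
}

running_mean <- function(v, k) {
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - k, 1)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect bright particles in a phase image
#'
#' Local maxima (3 x 3) above a fraction of the global peak, thinned so no
#' two detections are closer than `min_separation`. Strongest peaks win
#' ties.
#'
#' @param phase A `phase_image`.
#' @param threshold_frac Intensity threshold as a fraction of the global
#'   maximum (default 0.5).
#' @param min_separation Minimum center-to-center distance in micrometers.
#' @param edge_margin Border strip in micrometers excluded from detection
#'   (integration and background-estimate edge effects live there).
#' @return data.frame with columns `x`, `y` (micrometers) and `value`.
#' @export
detect_particles <- function(phase, threshold_frac = 0.5, min_separation,
                             edge_margin = 0) {
  m <- phase$phase
  px <- phase$grid$pixel_size
  ny <- nrow(m); nx <- ncol(m)
  if (edge_margin > 0) {
    b <- ceiling(edge_margin / px)
    if (2 * b >= min(ny, nx)) stop("detect_particles: edge_margin too large")
    inner <- m[(b + 1):(ny - b), (b + 1):(nx - b)]
  } else {
    b <- 0L
    inner <- m
  }
  if (max(inner) == min(inner))  # featureless image: nothing to detect
    return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0)))
  thr <- threshold_frac * max(inner)
  cand <- which(inner >= thr, arr.ind = TRUE)
  cand <- cand + b  # back to full-image indices
  is_max <- apply(cand, 1, function(rc) {
    i <- rc[1]; j <- rc[2]
    win <- m[max(1, i - 1):min(ny, i + 1), max(1, j - 1):min(nx, j + 1)]
    m[i, j] >= max(win)
  })
  cand <- cand[is_max, , drop = FALSE]
  if (!nrow(cand)) return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0)))
  vals <- m[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; vals <- vals[ord]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    d2 <- (prev[, 1] - cand[i, 1])^2 + (prev[, 2] - cand[i, 2])^2
    keep[i] <- all(d2 * px^2 >= min_separation^2)
  }
  data.frame(x = (cand[keep, 2] - 1) * px,
             y = (cand[keep, 1] - 1) * px,
             value = vals[keep])
}

#' Average line trace through detected particles
#'
#' Extracts, for every detection, the phase profile along the shear axis
#' (or the perpendicular) through the particle center, and averages the
#' profiles on a common center-relative coordinate grid. Detections closer
#' than `half_window` to the image edge are skipped with a warning.
#' Averaging n traces with independent noise reduces the trace variance by
#' ~ n.
#'
#' @param phase A `phase_image`.
#' @param detections data.frame with `x`, `y` centers in micrometers (as
#'   from [detect_particles()]).
#' @param half_window Half-length of the trace in micrometers.
#' @param axis `"x"` (shear axis, default) or `"y"`.
#' @return data.frame with `position` (micrometers, centered on the
#'   particle), `value` (mean phase, radians) and attribute `n_particles`.
#' @export
average_particle_trace <- function(phase, detections, half_window, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (!nrow(detections)) stop("average_particle_trace: empty detection list")
  m <- phase$phase
  px <- phase$grid$pixel_size
  ny <- nrow(m); nx <- ncol(m)
  k <- floor(half_window / px)
  offs <- (-k):k
  traces <- list()
  for (i in seq_len(nrow(detections))) {
    cj <- round(detections$x[i] / px) + 1
    ci <- round(detections$y[i] / px) + 1
    ok <- if (axis == "x") (cj - k >= 1 && cj + k <= nx && ci >= 1 && ci <= ny)
          else (ci - k >= 1 && ci + k <= ny && cj >= 1 && cj <= nx)
    if (!ok) {
      warning(sprintf("detection %d at (%g, %g) is within half a window of the edge; skipped",
                      i, detections$x[i], detections$y[i]))
      next
    }
    traces[[length(traces) + 1]] <-
      if (axis == "x") m[ci, cj + offs] else m[ci + offs, cj]
  }
  if (!length(traces)) stop("average_particle_trace: no usable detections")
  avg <- Reduce(`+`, traces) / length(traces)
  out <- data.frame(position = offs * px, value = avg)
  attr(out, "n_particles") <- length(traces)
  out
}

#' Gaussian fit of a peaked profile and its FWHM
#'
#' Least-squares fit of `A * exp(-(x - mu)^2 / (2 * sigma^2)) + c0` to a
#' single-peaked profile (Levenberg-Marquardt). The full width at half
#' maximum is `2 * sqrt(2 * log(2)) * sigma ~ 2.3548 * sigma`, with its
#' standard error propagated from the fit covariance. A constant offset is
#' always included for robustness against residual background.
#'
#' @param profile data.frame with columns `position` and `value` (as from
#'   [average_particle_trace()]), or a numeric vector with a `position`
#'   attribute.
#' @return An object of class `profile_fit`: fields `fwhm`, `fwhm_se`,
#'   `amplitude`, `center`, `sigma`, `offset`, `n_particles`, `fit`.
#' @examples
#' x <- seq(-5, 5, 0.05)
#' f <- fwhm_gaussian_fit(data.frame(position = x, value = exp(-x^2 / 2)))
#' f$fwhm  # 2.3548
#' @export
fwhm_gaussian_fit <- function(profile) {
  x <- profile$position
  y <- profile$value
  if (length(x) < 5) stop("fwhm_gaussian_fit: profile too short")
  c00 <- min(y)
  A0 <- max(y) - c00
  mu0 <- x[which.max(y)]
  above <- x[y - c00 > A0 / 2]
  sg0 <- max(diff(range(above)) / 2.3548, diff(range(x)) / 20)
  model <- function(p) p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4]
  # Levenberg-Marquardt on the residuals directly: unlike the nls wrappers
  # this handles zero-residual (noiseless) profiles.
  fit <- minpack.lm::nls.lm(
    par = c(A = A0, mu = mu0, sg = sg0, c0 = c00),
    fn = function(p) y - model(p),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!(fit$info %in% 1:4)) {
    stop(sprintf(
      "fwhm_gaussian_fit: fit did not converge (%s); residual norm = %.4g",
      fit$message, sqrt(fit$deviance)))
  }
  co <- fit$par
  dof <- max(length(y) - 4, 1)
  sigma2 <- fit$deviance / dof
  # vcov from the analytic Jacobian at the optimum: sigma^2 (J'J)^-1
  e <- exp(-(x - co[["mu"]])^2 / (2 * co[["sg"]]^2))
  J <- cbind(e,
             co[["A"]] * e * (x - co[["mu"]]) / co[["sg"]]^2,
             co[["A"]] * e * (x - co[["mu"]])^2 / co[["sg"]]^3,
             1)
  se <- tryCatch(sqrt(diag(solve(crossprod(J))) * sigma2),
                 error = function(e) rep(NA_real_, 4))
  k <- 2 * sqrt(2 * log(2))
  structure(list(fwhm = k * abs(co[["sg"]]),
                 fwhm_se = k * se[[3]],
                 amplitude = co[["A"]], center = co[["mu"]],
                 sigma = abs(co[["sg"]]), offset = co[["c0"]],
                 n_particles = attr(profile, "n_particles") %||% NA_integer_,
                 data = data.frame(position = x, value = y),
                 fit = fit),
            class = "profile_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf("<profile_fit> FWHM = %.4g +/- %.3g um, amplitude %.4g rad, center %.4g um (n = %s)\n",
              x$fwhm, x$fwhm_se, x$amplitude, x$center,
              ifelse(is.na(x$n_particles), "?", x$n_particles)))
  invisible(x)
}

#' Averaged phase profile along a line segment
#'
#' Samples the phase along the segment `from` -> `to` at pixel pitch, at
#' each position averaging over the transverse `width` (bilinear
#' interpolation). This is the standard way to plot how the phase varies
#' along an elongated specimen.
#'
#' @param phase A `phase_image`.
#' @param from,to Numeric `(x, y)` endpoints in micrometers, inside the
#'   image.
#' @param width Transverse averaging width in micrometers.
#' @return data.frame with `position` (micrometers from `from`) and `value`.
#' @export
radial_profile <- function(phase, from, to, width) {
  m <- phase$phase
  px <- phase$grid$pixel_size
  xmax <- (phase$grid$nx - 1) * px; ymax <- (phase$grid$ny - 1) * px
  for (p in list(from, to))
    if (p[1] < 0 || p[1] > xmax || p[2] < 0 || p[2] > ymax)
      stop("radial_profile: segment endpoint outside the image")
  L <- sqrt(sum((to - from)^2))
  if (L == 0) stop("radial_profile: zero-length segment")
  dir <- (to - from) / L
  nrm <- c(-dir[2], dir[1])
  npos <- max(2L, floor(L / px) + 1L)
  pos <- seq(0, L, length.out = npos)
  ntr <- max(1L, floor(width / px) + 1L)
  toff <- if (ntr == 1) 0 else seq(-width / 2, width / 2, length.out = ntr)
  vals <- vapply(pos, function(s) {
    pts_x <- from[1] + s * dir[1] + toff * nrm[1]
    pts_y <- from[2] + s * dir[2] + toff * nrm[2]
    mean(bilinear_sample(m, px, pts_x, pts_y))
  }, numeric(1))
  data.frame(position = pos, value = vals)
}

# bilinear interpolation at object-space coordinates, clamped to the grid
bilinear_sample <- function(m, px, xs, ys) {
  ny <- nrow(m); nx <- ncol(m)
  fx <- pmin(pmax(xs / px, 0), nx - 1)
  fy <- pmin(pmax(ys / px, 0), ny - 1)
  j0 <- pmin(floor(fx), nx - 2); i0 <- pmin(floor(fy), ny - 2)
  tx <- fx - j0; ty <- fy - i0
  idx <- function(i, j) m[cbind(i + 1, j + 1)]
  (1 - tx) * (1 - ty) * idx(i0, j0) + tx * (1 - ty) * idx(i0, j0 + 1) +
    (1 - tx) * ty * idx(i0 + 1, j0) + tx * ty * idx(i0 + 1, j0 + 1)
}
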