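# Internal FFT helpers shared by the forward model and the reconstruction
# code. All images are ny x nx matrices indexed [y, x]: rows are y, columns
# are x, and x is the shear / gradient axis.

# Angular frequency samples (rad per unit length) in FFT order for an n-point
# grid with spacing d. The Nyquist bin of an even-length grid is kept at its
# positive value; callers that build odd (sign-antisymmetric) filters must
# zero it themselves.
fft_omega <- function(n, d = 1) {
  i <- c(0:(n %/% 2), if (n > 1) -((n - n %/% 2 - 1):1)) # 0,1,..,n/2,-(n/2-1),..,-1
  2 * pi * i[seq_len(n)] / (n * d)
}

# Circular convolution of a real image with a real kernel sampled in FFT
# order (kernel origin at element [1,1]).
fft_convolve <- function(img, kernel_fft_order) {
  stopifnot(all(dim(img) == dim(kernel_fft_order)))
  Re(stats::fft(stats::fft(img) * stats::fft(kernel_fft_order), inverse = TRUE)) /
    length(img)
}

# Band-limited (Fourier interpolation) shift of an image by (dx, dy) in
# pixel units; out(x, y) = in(x + dx, y + dy). Periodic boundary.
fft_shift_image <- function(img, dx = 0, dy = 0) {
  ny <- nrow(img); nx <- ncol(img)
  kx <- fft_omega(nx); ky <- fft_omega(ny)
  # A pure translation must not create an imaginary part, so the unpaired
  # Nyquist bin of even-length axes is dropped from the ramp.
  if (nx %% 2 == 0) kx[nx %/% 2 + 1] <- 0
  if (ny %% 2 == 0) ky[ny %/% 2 + 1] <- 0
  ramp <- exp(1i * (outer(ky * dy, rep(1, nx)) + outer(rep(1, ny), kx * dx)))
  Re(stats::fft(stats::fft(img) * ramp, inverse = TRUE)) / length(img)
}

# Radial pupil transfer of the quasi-coherent model: the objective pupil
# disc (radius ko, rad/um) smoothed by the condenser source disc (radius
# kc). T(k) is the normalized overlap area of the two discs at center
# separation k: flat at 1 up to ko - kc, rolling off to 0 at ko + kc. With
# kc = 0 it degenerates to the hard coherent pupil.
pupil_transfer <- function(k, ko, kc) {
  if (kc <= 0) return(as.numeric(k <= ko))
  t <- numeric(length(k))
  inside <- k <= abs(ko - kc)
  outside <- k >= ko + kc
  mid <- !inside & !outside
  t[inside] <- 1
  if (any(mid)) {
    d <- k[mid]
    a1 <- ko^2 * acos(pmin(pmax((d^2 + ko^2 - kc^2) / (2 * d * ko), -1), 1))
    a2 <- kc^2 * acos(pmin(pmax((d^2 + kc^2 - ko^2) / (2 * d * kc), -1), 1))
    a3 <- 0.5 * sqrt(pmax((-d + ko + kc) * (d + ko - kc) *
                          (d - ko + kc) * (d + ko + kc), 0))
    t[mid] <- (a1 + a2 - a3) / (pi * min(ko, kc)^2)
  }
  t
}

# Apply the radially symmetric pupil transfer to a complex field matrix.
fft_pupil_filter <- function(field, pixel_size, ko, kc = 0) {
  ny <- nrow(field); nx <- ncol(field)
  kx <- fft_omega(nx, pixel_size); ky <- fft_omega(ny, pixel_size)
  K <- sqrt(outer(ky^2, kx^2, `+`))
  Tm <- matrix(pupil_transfer(as.vector(K), ko, kc), ny, nx)
  stats::fft(stats::fft(field) * Tm, inverse = TRUE) / length(field)
}

# Run code with a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards so library calls stay reproducible
# without clobbering the session RNG.
with_private_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
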