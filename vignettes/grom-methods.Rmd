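---
title: "Phase-shifted DIC quantitative phase imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-shifted DIC quantitative phase imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(grom)
```

`grom` simulates and reconstructs quantitative phase images (QPI) for a
differential interference contrast (DIC) microscope upgraded with a liquid
crystal retarder in the illumination path — gradient retardance optical
microscopy (GROM). The retarder imposes a controllable phase bias between
the two sheared, orthogonally polarized beams of the DIC interferometer, so
a series of images at known biases can be demodulated into the specimen's
phase gradient and integrated into quantitative phase. The package
implements the complete desk-scale counterpart of that instrument: phantom
generation, image formation, phase-shifting demodulation, gradient
integration, background correction, and the validation metrics used to
qualify such systems (peak phase of calibration beads, Gaussian-fit FWHM,
line profiles).

## Image formation

A pure-phase specimen delays the extraordinary and ordinary waves by the
phase it presents at two laterally sheared positions. With unit amplitudes,
wave phases $\theta_e(x,y) = \Phi(x + s/2, y)$ and
$\theta_o(x,y) = \Phi(x - s/2, y)$, and a retarder bias $\alpha$ on the
o-wave, the camera sees the two-beam interference

$$I(\alpha) = J_o^2 + J_e^2 + 2 J_o J_e
  \cos(\theta_e - \theta_o - \alpha).$$

The shear distance $s$ is below the PSF width in any DIC system; the package
defaults to half the incoherent PSF FWHM ($0.514\,\lambda/\mathrm{NA}$) and
treats $s$ as a free calibration parameter, since commercial prisms do not
document it. The half-shears are applied to the *phase maps* by band-limited
Fourier interpolation (symmetric $\pm s/2$), matching the two-beam geometry
rather than shifting intensities.

### Diffraction model

`acquire_bias_series()` offers three blur models. The default, `"coherent"`,
filters each complex wave $J e^{i\theta}$ with the objective pupil before
interference. The pupil edge is smoothed by the condenser source: the radial
transfer is the normalized overlap area of the objective pupil disc (radius
$\mathrm{NA}_{obj}/\lambda$) and the condenser source disc (radius
$\mathrm{NA}_{cond}/\lambda$) — flat to
$\mathrm{NA}_{obj}-\mathrm{NA}_{cond}$, rolling off to
$\mathrm{NA}_{obj}+\mathrm{NA}_{cond}$. This is the leading-order
partial-coherence correction for a Koehler system whose condenser NA (0.30
here) sits well below the objective NA; a hard-edged pupil
(`na_condenser = 0`) produces Gibbs overshoot of several percent on
micron-scale phase objects, which the source smoothing physically removes.
An `"incoherent"` model (per-frame convolution with the normalized Airy
intensity PSF, `psf_blur()`) is retained for comparison; it strongly
attenuates the phase amplitude of resolved objects (a 1 µm bead loses ~30%
of its peak) and is not appropriate for near-coherent DIC, but it is the
correct model for intensity-only measures.

Shot noise is Poisson per pixel at a user-set budget of photons per unit
intensity, seeded and reproducible (`add_shot_noise()`).

What the simulation does *not* model: objective aberrations and defocus,
the 20 nm illumination bandwidth (it mainly suppresses speckle, which the
simulation does not generate), polarization imperfections, the Wollaston
prism geometry, rigorous partially coherent (Abbe/Hopkins) source
integration, and multiple scattering in thick tissue. Consequences are
discussed under *Limitations*.

## Phantoms

`make_sphere_phantom()` evaluates, at pixel centers, the chord length
$t(\rho) = 2\sqrt{r^2-\rho^2}$ through each dielectric sphere and converts
it to optical phase $(2\pi/\lambda)\,\Delta n\, t$. The peak of a bead of
diameter $d$ is $(2\pi/\lambda)\,\Delta n\, d$ — for a 1 µm polystyrene
bead ($n \approx 1.588$ at 650 nm) in $n = 1.518$ immersion oil this is
0.677 rad, the standard bead-calibration value (approximately 0.68 rad).
Polystyrene dispersion places its index near 1.587–1.589 in the red; the
package documents 1.588 as the 650 nm value and requires `n_particle`
explicitly, since a sodium-line value of 1.59 shifts the expected peak by
+0.02 rad. Pixel-center sampling (no area-weighted anti-aliasing) keeps the
generator simple and convergent; peak and integrated phase converge as the
grid is refined, and the integrated phase matches the analytic sphere
volume to 1% at 20 pixels per diameter.

Flat phantoms and band-limited random fields (Gaussian spectrum, seeded,
zero mean, bounded amplitude) support calibration and property tests.

## Demodulation

With the four quadrature biases $\{0, \pi/2, \pi, 3\pi/2\}$,

$$\nabla_x\Phi = \operatorname{atan2}(I_{\pi/2} - I_{3\pi/2},\;
  I_0 - I_{\pi}),$$

and for an arbitrary schedule $\alpha_i$ with spacings $\Delta\alpha_i$ the
quadrature sums $\sum_i I(\alpha_i)\sin(\alpha_i)\Delta\alpha_i$ and
$\sum_i I(\alpha_i)\cos(\alpha_i)\Delta\alpha_i$ enter the same
two-argument arctangent. Conventions that matter:

* **Sign.** A common published form of the N-step estimator carries a
  leading minus sign, which contradicts the four-step formula on identical
  data. The package fixes one convention — positive gradient for
  $\theta_e > \theta_o$ — for both estimators; on a uniform full-period
  schedule they agree to machine precision.
* **Quadrants.** `atan2` is used throughout; the arctangent of a ratio
  cannot distinguish opposite quadrants.
* **Degenerate pixels.** Where both quadrature sums vanish (no modulation)
  the gradient is set to 0 and flagged in a validity mask, so downstream
  Fourier operations always see finite arrays. No phase unwrapping is
  applied; all supported specimens keep $|\nabla_x\Phi| < \pi$.

The demodulated value is exactly $\theta_e-\theta_o$ for noiseless frames —
including under the coherent blur model, where it equals the phase of the
pupil-filtered field product — so the whole observable chain is invertible
up to diffraction.

Averaging more bias steps at a fixed per-frame photon budget reduces the
background gradient noise like $1/\sqrt{N}$ (`sensitivity_experiment()`
reproduces the scaling within a few percent), which is why a 16-step series
resolves specimens that a 4-step series buries in noise.

## Gradient integration

The acquired gradient is a finite difference over the shear distance, with
row-wise transfer $H(k) = 2i\sin(ks/2)$. `integrate_hilbert()` inverts it in
the Fourier domain row by row: rows are extended antisymmetrically to twice
their length (the gradient is derivative-like, so this corresponds to a
mirror extension of the phase and suppresses wrap-around artifacts), the
spectrum is divided by $H(k)$, and two conventions close the inversion:

* the $k=0$ component is zeroed and each row is re-anchored at
  $\Phi(0, y) = 0$ — the integration constant is not observable, and the
  package adopts the convention that the field of view starts in clean
  background;
* where the shear spans more than two pixels, $H$ also vanishes at in-band
  frequencies $k = 2\pi m/s$, $m \ge 1$. Those components are annihilated
  by the acquisition — they are unobservable — so the filter zeroes a
  narrow notch around them ($|ks/2 - m\pi| < 0.05$, capping the local gain
  at 20) instead of amplifying noise without bound. The low-frequency
  branch keeps the exact inverse: its $1/(ks)$ gain is inherent to
  integrating a gradient and is dealt with by background correction, not by
  biasing the filter.

For small $ks$ the filter reduces to $1/(iks)$, the classic Hilbert-kernel
(signum) integration. A 1-D row-wise inversion is used; a 2-D half-plane
variant exists in the literature but shares the same along-shear transfer,
and the row-wise form matches the line-integral definition directly.

Two baselines are included. `integrate_cumulative()` is the literal running
sum — exact for noiseless data, but each row random-walks under noise
(variance grows linearly along the scan), producing the familiar streaks.
`wiener_deconvolve()` applies the regularized inverse
$\bar H/(|H|^2 + 1/\mathrm{snr})$. The Wiener filter has *lower* RMS error
under heavy noise — Tikhonov regularization trades bias for variance — but
the bias falls exactly on the low frequencies that carry a specimen's phase
amplitude: on a 1 µm bead it depresses the peak by ≈0.03 rad even without
noise, while the exact inversion is unbiased (−0.003 rad). On the
peak-amplitude metric by which bead reconstructions are validated, the
Fourier/Hilbert integration therefore outperforms Wiener deconvolution at
every noise level tested, consistent with the practical preference for the
Hilbert route in phase-shifted DIC work.

## Background correction

`background_correct()` subtracts a morphological background: a grayscale
opening with a sliding-paraboloid structuring element (the smooth variant of
the rolling ball, as in common image-analysis software), implemented as
separable parabolic min/max convolutions. The paraboloid has lateral radius
$R$ and depth equal to the image dynamic range; features narrower than $R$
ride on top of the estimated background. Two refinements keep the estimate
unbiased: the ball rolls on a 3×3 box-smoothed copy (so it does not chase
single-pixel minima), and the subtracted background is recentred so the
median of the corrected image is zero — an opening is a lower envelope and
would otherwise shift a noisy background upward by the envelope depth.
Recentring assumes sparse specimens (the median pixel is background), which
holds for every supported phantom. The paraboloid lifts by
$\mathrm{depth}\cdot(w/R)^2$ when bridging a feature of half-width $w$, so
$R$ should be several times the largest feature; the reconstruction wrapper
defaults to 50 PSF FWHM capped at a quarter of the field. Opening with a
fixed element is idempotent; passing `depth` explicitly reuses the identical
element across calls.

## Metrics

* `peak_phase()` — the maximum of the box-filtered image (default 3×3);
  robust to single-pixel noise, and within a percent of the true peak for
  well-sampled beads.
* `detect_particles()` — 3×3 local maxima above half the global peak,
  thinned to a minimum separation, with an edge margin to avoid
  integration/background edge effects.
* `average_particle_trace()` — along-shear traces through detected centers,
  averaged on a center-relative grid. Detected centers are pixel-quantized;
  with beads at arbitrary sub-pixel positions this registration jitter is
  part of the measured width, as on the bench.
* `fwhm_gaussian_fit()` — Levenberg–Marquardt fit of
  $A\exp(-(x-\mu)^2/2\sigma^2) + c$ on the residuals directly
  (`minpack.lm::nls.lm`; the `nls` wrappers reject zero-residual noiseless
  profiles), $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$, standard errors from
  the analytic Jacobian. The offset term is always included: residual
  pedestals survive even good background correction. Note that the
  least-squares Gaussian fit of non-Gaussian profiles is a definition, not
  an approximation guarantee — for a top-hat of width $w$ it converges to
  ≈0.86 $w$.
* `radial_profile()` — transverse-averaged line profile along an arbitrary
  segment, for elongated specimens (e.g. verifying that phase rises toward
  a denser structure end).

`bead_peak_experiment()` and `bead_resolution_experiment()` package the two
standard calibrations end to end. The resolution experiment uses a higher
default photon budget (10⁵ per unit intensity) than the peak validation
(10⁴): resolution calibrations are acquired bright so that the fitted width,
not noise-driven detection jitter, limits the measurement. Twenty replicate
beads are averaged, matching standard practice.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale: 384² pixels
at the 40× camera sampling (46 nm) for the peak validation, 128² at Nyquist
sampling ($\lambda/4\mathrm{NA}$) with 20 replicates for each resolution
measurement, 64² with 10 replicates for the step-count sensitivity ladder,
and 16–96² grids for property tests. These sizes keep every quantity's
Monte-Carlo error well inside the tolerances asserted while remaining
seconds-fast; they are package choices, and all experiments accept larger
grids and replicate counts unchanged.

Floating-point conventions: images are stored as 32-bit TIFF rescaled to
the writer's [0, 1] range with the physical range in the plain-text
sidecar, so round trips are exact to float32 quantization (~10⁻⁷ of the
range); all seeded randomness uses a private RNG stream and restores the
session state.

## Limitations

* The quasi-coherent model is accurate when
  $\mathrm{NA}_{cond} \ll \mathrm{NA}_{obj}$ (the 40×/0.75 case,
  $\sigma = 0.4$). At 20×/0.40 the same condenser gives $\sigma = 0.75$ —
  substantially partially coherent — and the model under-predicts measured
  profile widths there: the simulated 1 µm-bead FWHM is ~1.0 µm where bench
  measurements of such systems report ~1.3 µm. Full source integration
  (out of scope here) narrows but does not close that gap; residual
  defocus and aberrations of low-magnification objectives are the likely
  remainder. Treat low-NA resolution figures from the simulator as lower
  bounds.
* Axial behavior is not modeled: z-stacks are processed plane by plane
  (`reconstruct_volume()`), with no optical sectioning theory or axial
  deconvolution.
* No phase unwrapping: gradients beyond $\pm\pi$ per shear alias.
* Absorbing specimens are supported through an amplitude map but are not
  validated against any physical reference.
* The synthetic generator covers spheres, flats, and smooth random fields.
  Passing its tests demonstrates the correctness of the demodulation and
  integration chain and the fidelity of the diffraction model at high NA;
  it does not certify performance on scattering, optically thick tissue.
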