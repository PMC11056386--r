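# grom

Simulation and quantitative phase reconstruction for gradient retardance
optical microscopy (GROM) — phase-shifted differential interference
contrast (DIC) imaging.

## The problem

A DIC microscope is a shear interferometer: a Wollaston prism splits the
illumination into two orthogonally polarized beams separated laterally by a
shear distance `s` smaller than the point-spread-function width. After the
specimen, the beams recombine and interfere, so the image encodes the
specimen's phase *gradient* along the shear axis. Adding a liquid-crystal
retarder to the illumination path makes the phase bias `α` between the two
beams programmable, and a series of images at known biases can be
demodulated into a quantitative gradient-phase map and integrated into the
specimen's optical phase `ΔΦ(x, y)` — the quantity that converts to dry
mass and density in label-free cell biology.

`grom` is the software half of such an instrument, for people building or
validating one: it simulates phase-shifted DIC acquisitions of known
specimens (calibration beads, flats, random fields) with diffraction and
shot noise, reconstructs quantitative phase from real or simulated bias
stacks, and measures the validation quantities the field reports.

## The model

Image formation at bias `α` (field amplitudes `J`, phases `θ`):

    I = J_o² + J_e² + 2·J_o·J_e·cos(θ_e − θ_o − α),
    θ_e(x, y) = Φ(x + s/2, y),   θ_o(x, y) = Φ(x − s/2, y).

Demodulation — four-step and N-step phase-shifting interferometry:

    ∇ₓΦ = atan2(I_{π/2} − I_{3π/2}, I_0 − I_π)
    ∇ₓΦ = atan2(Σᵢ I(αᵢ)·sin(αᵢ)·Δαᵢ, Σᵢ I(αᵢ)·cos(αᵢ)·Δαᵢ)

Integration — Fourier inversion of the shear-difference transfer
`H(k) = 2i·sin(k·s/2)` along the shear axis (the Hilbert-kernel method),
with the integration constant fixed by `Φ(0, y) = 0`; cumulative-sum and
Wiener-deconvolution baselines; sliding-paraboloid (rolling-ball)
background correction.

Validation metrics: the peak phase of a bead of diameter `d` and index
contrast `Δn` is `(2π/λ)·Δn·d` — 0.68 rad for a 1 µm polystyrene bead
(n ≈ 1.588 at 650 nm) in n = 1.518 oil — and planar resolution is the
full width at half maximum of a Gaussian fit to the averaged trace of
replicate beads.

## Worked example

Simulate a 16-bias series of a 1 µm polystyrene bead in oil through a
40×/0.75 NA system with shot noise, then reconstruct and evaluate — from R:

```r
library(grom)

cfg <- run_config(list(
  optics = list(wavelength = 0.65, na_objective = 0.75, na_condenser = 0.30,
                magnification = 40, camera_pixel = 1.85),
  grid = list(ny = 256, nx = 256),
  schedule = list(n = 16),
  phantom = list(type = "spheres", spheres = list(
    list(center = c(5.9, 5.9), diameter = 1.0,
         n_particle = 1.588, n_medium = 1.518))),
  blur = "coherent", noise = list(photons_per_unit = 1e4), seed = 7))

paths <- grom_simulate(cfg, "run")
grom_reconstruct(paths$stack, "run", background_radius = 4)
grom_evaluate("run/phase.tif", paths$truth)
```

or equivalently from the shell via the bundled wrapper
(`system.file("cli", "grom", package = "grom")`):

```sh
grom simulate    --config bead.yml --out run
grom reconstruct run/stack.tif --bg-radius 4 --out run
grom evaluate    run/phase.tif run/truth.tif --out run
```

Output of the run above:

```
      metric     value          se n units
1 peak_phase 0.6847319          NA 1   rad
2       fwhm 0.7320926 0.006689155 1    um

evaluate: RMS 0.01257 rad (0.01256 after DC removal), peak error +0.01305 rad
```

The reconstructed peak (0.685 rad) sits within a few percent of the
analytic bead phase `(2π/0.65)·0.070·1.0 = 0.677 rad`; the 0.73 µm trace
FWHM is the bead diameter convolved with the diffraction-limited PSF at
NA 0.75. The `run/` directory holds the multi-page stack, ground truth,
gradient and phase images (32-bit TIFF plus plain-text sidecars) and the
metrics table.

Higher-level calibration experiments are packaged directly:

```r
opt <- optical_config(0.65, na_objective = 0.75, magnification = 40)
bead_peak_experiment(opt, seed = 1)$peak          # robust pipeline peak (rad)
bead_resolution_experiment(opt, diameter = 0.2,
                           n_medium = 1.333)$fwhm # 20-bead FWHM (um)
sensitivity_experiment(make_flat_phantom(image_grid(64, 64, 0.1)),
                       opt, c(4, 8, 16, 32), 100, 10, seed = 1)
```

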