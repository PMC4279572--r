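---
title: "Methods: fiber-bundle integral-field Raman imaging at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fiber-bundle integral-field Raman imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibercube)
```

## The instrument model

A 20 × 20 matrix of 110/132 µm step-index fibers at 0.5 mm pitch samples
the optical image of the sample; the far ends of the 400 fibers form a
pseudo-slit feeding a spectrograph, so one CCD exposure carries 400 Raman
spectra as parallel *traces*. The geometry module encodes exactly this:
the active edge is the center-to-center span `(n − 1) · pitch` = 9.5 mm
(probe surface 9.5² ≈ 90 mm²), the light-collecting area is
`400 · π (55 µm)²` ≈ 3.80 mm², and hence only ≈ 4.2% of the image signal
enters a fiber core (the *fill factor*). Grid coordinates are 0-based
`(row, col)`, row 0 at the top of rendered images; the grid↔slit bijection
defaults to a row-major raster because the true fiber routing of a real
bundle is never guaranteed — it is configurable as an explicit mapping
table, and every downstream stage consumes only the bijection.

## What the simulator emulates — and what it does not

No public raw frames exist for this instrument class, so the simulator is
a first-class, tested module. It reproduces the statistical structure the
reduction relies on:

* **Detector**: 1200 × 600 px (cross-dispersion × dispersion), bias level
  100 counts, Gaussian read noise 3 counts rms, Poisson shot noise,
  unit gain. This is a desk-scale stand-in for a 4k × 4k science CCD —
  400 traces at 2.9 px pitch need ~1160 cross-dispersion pixels.
* **Traces**: Gaussian cross-profiles (σ = 0.55 px) along gently bowed
  (0.8 px) polynomial paths. The profile width was chosen *below* the
  naive "pitch/2.4" packing: at 2.9 px pitch a σ = 1.2 px profile would
  overlap its neighbours so strongly that tophat extraction could never
  meet a percent-level fidelity target (≈ half of a neighbour's flux would
  fall inside a 2.5σ aperture). With σ = 0.55 px the separation is > 5σ
  and residual crosstalk stays below ~1%.
* **Dispersion**: near-linear wavelength solutions spanning 788–938 nm
  over the 600 columns, with a small quadratic term and deterministic
  per-fiber zero-point offsets (±0.3 nm), excitation at 785 nm
  (Stokes side only). The synthetic arc has 8 lines evenly placed in
  790–930 nm; the calibration math is line-list agnostic.
* **Science exposures**: per spaxel, library peaks rendered as Gaussians
  (only the peak *positions* are literature values; unit relative
  amplitudes and 12 cm⁻¹ FWHM are simulator defaults), plus a positive
  4th-order polynomial fluorescence baseline (amplitude 2× the peak flux),
  an optional smooth optics background, a 2D-Gaussian illumination profile
  with a 10× center-to-corner ratio, fiber-to-fiber throughput scatter
  (lognormal, σ = 10%), dead fibers (zero throughput), and single-pixel
  cosmic-ray hits. Spectra are synthesized on an axis padded ±220 cm⁻¹
  beyond the requested cube axis so frames carry no artificial spectral
  edges.
* **SNR convention**: the `snr` parameter fixes the extracted peak
  signal-to-noise at the *dimmest substance-bearing spaxel* (shot +
  read noise over the extraction aperture). Anchoring at the dimmest
  spaxel, rather than the field center, is what makes "SNR ≥ 30"
  statements hold across the whole illuminated field.

Not emulated: absolute radiometry, detector cosmetics (hot columns,
fringing), scattered light, flexure, anti-Stokes spectra, and real
spectral line shapes or relative intensities. A green test therefore
establishes that the *pipeline machinery* is correct under the stated
noise model — not that the simulator reproduces any particular laboratory
measurement.

## Reduction: numerical choices

* **Master bias** is a per-pixel median (exact 3-frame median via a
  min/max identity; `apply` otherwise).
* **Trace finding** detects local maxima of the column-averaged profile
  above 5% of its range (background taken at the 2nd percentile — with
  densely packed narrow traces the profile *median* sits on-trace and
  must not be used). Centers, widths and amplitudes per column-bin come
  from a three-point log-parabola, which is exact for a sampled Gaussian;
  a second pass subtracts the modelled wings of the four nearest
  neighbours before re-estimating. A quadratic is then fitted per fiber.
  Measured accuracy on noisy flats: < 0.07 px worst case.
* **Dead fibers** leave no trace on the flat. By default a count mismatch
  is an error that names the count found; with `fill_missing = TRUE`
  (what the pipeline uses) interior gaps are inferred from the trace
  pitch and filled with interpolated, dead-flagged traces so the slit
  indexing of the surviving fibers stays correct.
* **Extraction** is a tophat of half-width 2σ whose sum is divided by the
  modelled in-aperture fraction of the Gaussian profile. The
  renormalization makes flux conservation exact (machine precision on
  noise-off frames) instead of ~95%; the 2σ width (rather than 2.5σ)
  keeps the aperture edge ≥ 1.9 px away from the neighbouring trace,
  bounding crosstalk at ~1% worst-case. Wider apertures trigger a
  cross-talk warning.
* **Wavelength calibration** centroids arc lines (±3 px windows), matches
  them to the sorted line list in order (order-based matching is
  deliberate: synthetic line lists are controlled, pattern matching is
  out of scope), and least-squares fits a degree-3 polynomial per fiber.
  Dead fibers inherit the median solution but stay flagged. Typical
  residual RMS: ~0.002 nm.
* **Cosmic-ray cleaning** operates on extracted spectra. A sample is
  replaced by the running median (window 9) when its residual exceeds
  k = 6 robust sigma *and* its larger neighbour's residual is below 0.35×
  its own. The width test is essential: a genuine 12 cm⁻¹ Raman peak is
  only ~3.6 extracted samples wide, and plain sigma-clipping would
  decapitate it, while a cosmic hit is strictly single-sample. The noise
  scale interpolates the robust sigma between the low- and high-signal
  halves of the spectrum, since shot noise makes residuals
  heteroscedastic. Passes iterate to a fixpoint, making the operation
  idempotent.

## Cube, baseline, normalization, maps

Wavelengths convert to Raman shift as Δν̃ = 10⁷(1/785 − 1/λ) cm⁻¹;
anti-Stokes wavelengths are a domain error. Spectra are linearly
interpolated onto a common 200–2000 cm⁻¹ axis at 2 cm⁻¹ (covering every
library peak, 292–1703 cm⁻¹; the true spectral sampling of the reduced
cubes is an implementation choice), and cube assembly is a pure
re-indexing through the slit bijection with an explicit dead-spaxel mask —
masked spaxels carry no interpolated values and render white.

The fluorescence baseline uses the iterative modified polynomial fit:
fit an order-4 polynomial (ordinary least squares on the axis rescaled to
[−1, 1] for conditioning), replace the working spectrum by the pointwise
minimum of itself and the fit, repeat 15 times. The working spectrum is
non-increasing by construction, so the estimate relaxes under the peaks;
on a pure polynomial it is an exact fixed point, and on
baseline + single peak it recovers peak heights to a few percent. The
same code path and defaults serve every baseline-removal use in the
package.

Reference handling is two-step: per-channel subtraction of a blank
(optics background) cube, then per-spaxel *scalar* division by a summary
of a uniform reference exposure — the mean over the full axis by default,
a configurable band otherwise. Scalar (not per-channel) normalization is
the default because only the illumination profile, not the spectral
response, needs removing; per-channel division would also amplify
channel noise in the reference.

Chemical maps fit `offset + A·exp(−(x−c)²/2σ²)` in a 40 cm⁻¹ window at
the substance's characteristic shift after baseline removal; the map
value is the fitted height `A` (clamped at 0; non-convergence yields a
flagged 0, never an exception). σ is confined to `[step/2, window/4]`:
unconstrained, the Gaussian-plus-offset model is degenerate — a broad,
low pedestal fits any flat noisy window with a spuriously large
amplitude. Overlays assign each spaxel the color of the map with the
largest height normalized by that map's own maximum, above a 20%
detection threshold (a choice this package makes; "detected location"
needs one); ties resolve to the first map in the list for determinism,
and damaged fibers are marked brown.

## Design choices made where the design was open

* Slit ordering: row-major raster by default, arbitrary bijections
  supported (the physical routing is undocumented for real bundles).
* The default pipeline configuration includes one dead fiber at grid
  (12, 5), mirroring the defective-fiber display convention; set
  `layout$dead_fibers = NULL` for a pristine bundle.
* All randomness flows from one top-level seed via `stage_seed()`, so
  reruns are bit-identical and stages are independently reseedable.
* FITS is the carrier for frames, row-stacked spectra, cubes and maps
  (64-bit float images, linear spectral WCS keys, masks as extensions),
  written by a minimal self-contained reader/writer; YAML for configs,
  JSON for run reports. Every product records the config hash and seed.

## Known limitations

Tophat extraction with renormalization is not optimal (variance-weighted)
extraction and performs no crosstalk deblending; scattered light and
flexure are unmodelled; order-based arc matching assumes a controlled
line list; quantitative concentration calibration is out of scope (map
heights are relative). The suite's empirical statements — trace accuracy,
flux conservation, wavelength residuals, baseline recovery, bead-phantom
segmentation — are exactly those computed by the tests and the acceptance
script, under the simulator's stated world.
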