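# shgoptics

Quantitative analysis of fibrillar collagen architecture from second
harmonic generation (SHG) microscopy combined with bulk optical
scattering measurements — the measurement chain used to compare normal
and fibrotic (e.g. idiopathic pulmonary fibrosis) tissue.

Collagen's sub-resolution assembly is not directly imageable, but it
leaves quantitative optical fingerprints. This package implements the
estimators for each of them, the Monte Carlo photon-transport forward
model that connects them to what detectors actually record, and a
synthetic-data generator with known ground truth so the whole pipeline
is testable without tissue data:

* **Bulk optics** — scattering coefficient μs from Beer–Lambert
  attenuation, `I = α I₀ exp(−d μs)` (absorption negligible in
  collagen-rich tissue); effective anisotropy g_ef from a
  Henyey–Greenstein fit to goniometry,
  `p(θ) = a (1 − g²) / (1 + g² − 2 g cos θ)^{3/2}`; a Monte Carlo
  lookup inversion correcting g_ef for multiple scattering to the true
  single-scattering g; the reduced scattering coefficient
  `μs' = μs (1 − g)`; and the Whittle–Matérn spectral fit
  `μs'(λ) ∝ λ^{2m−4}`, whose shape factor m is half the mass fractal
  dimension of the sub-resolution structure.
* **SHG emission directionality** — the intrinsic creation ratio
  F_SHG/B_SHG (set by the phase mismatch Δk = k_2ω − 2k_ω, a proxy for
  fibril size and axial packing) extracted from depth-resolved
  forward/backward image stacks by reduced chi-squared matching of
  Monte Carlo forward-model curves, whole-field and on 15 × 15-pixel
  patches (≈ 5.3 µm) for heterogeneity mapping.
* **Polarization-resolved SHG** — per-pixel fits of the single-axis
  C6v intensity model give the tensor ratio b = χ_ZZZ/χ_ZXX and the
  α-helical pitch angle θp = arctan(√2/b).
* **SHG circular dichroism** — the normalized per-pixel asymmetry
  |I_LHCP − I_RHCP| / ½(I_LHCP + I_RHCP), a chirality readout.
* **Morphology and statistics** — packing efficiency (above-threshold
  pixel fraction) and the group-comparison protocol (one-way ANOVA
  with Student's t or Tukey HSD, α = 0.05).

Everything is tidyverse-styled: tabular inputs and outputs are tibbles,
fitted objects have `tidy()`/`glance()` methods and `autoplot()`
figures; image stacks are light S3 containers around count matrices.

## Worked example

Synthesize a depth-resolved detector stack pair with a known creation
ratio under normal-lung optics at the SHG wavelength, then recover the
ratio from the images alone:

```r
library(shgoptics)

optics <- optical_properties(445, mus = 327, g_single = 0.914)
#> Optical properties at 445 nm: mus = 327 cm^-1, g = 0.914, mus' = 28.122 cm^-1

phantom <- fiber_phantom_config(image_size = 64, n_fibers = 15, seed = 11)
gen <- make_depth_stack(phantom, R = 2.67, optics,
                        slab_geometry(0.02), detection_geometry(),
                        depths_um = seq(5, 95, by = 10),
                        mc = mc_config(1e5, seed = 77))

profile <- measure_fb_profile(gen$pair)
head(profile, 3)
#>   depth_um fb_measured   fb_se n_pixels valid
#> 1        5        1.10 0.00325     2854 TRUE
#> 2       15        1.23 0.00354     2870 TRUE
#> 3       25        1.34 0.00378     2895 TRUE

fit <- extract_creation_ratio(profile, optics, slab_geometry(0.02),
                              detection_geometry(),
                              mc_config(1e5, seed = 123))
fit
#> SHG creation-ratio fit: F_SHG/B_SHG = 2.673 (reduced chi^2 = 29.2, 10 depths)
```

The measured F/B climbs from 1.10 at 5 µm to ~2.5 at 95 µm — scattering
redirects a depth-dependent share of the forward-emitted photons — and
the chi-squared grid search deconvolves that propagation to recover the
generating ratio 2.67 to within 0.01. The spectral fit and pitch-angle
relation are one-liners:

```r
fit_whittle_matern(make_spectral_dataset(m = 1.61, amplitude = 6e5))
#> Whittle-Matern spectral fit: m = 1.6100 (exponent -0.7800, fractal dimension 3.2200)

pitch_angle(sqrt(2) / tan(48.25 * pi / 180))
#> [1] 48.25
```

See the vignette (`vignettes/shg-collagen-analysis.Rmd`) for the model
assumptions, numerical choices and the limits of what the synthetic
phantoms emulate.

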