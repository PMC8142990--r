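# qpmsizer

Single-particle sizing of nanoscale vesicles (liposomes) by quantitative
phase microscopy (QPM), as a tested, reusable R package with a command-line
interface.

Dynamic light scattering — the workhorse for liposome characterization —
reports an intensity-weighted ensemble distribution in which the scattered
intensity grows as the sixth power of the diameter, so large particles
dominate and polydisperse or out-of-range samples fit poorly. QPM offers a
label-free, single-particle alternative: particles below the diffraction
limit cannot be sized laterally (they all appear PSF-sized), but their
*phase* is measured with nanometric optical-path sensitivity, and for an
immobilized spherical vesicle the apex optical thickness equals its
diameter.

## The model

A phase-shifting interferometer records M fringe images

&nbsp;&nbsp;&nbsp;&nbsp;*I*ᵣ(x,y) = *A*(x,y) + *B*(x,y)·cos[φ(x,y) + δᵣ],&nbsp;&nbsp;r = 1…M,

where *A* is the background, *B* the modulation, φ the specimen phase and
δᵣ the per-frame phase shift. Substituting a = A, b = B·cos φ,
c = −B·sin φ makes the model linear per pixel,
*I*ᵣ = a + b·cos δᵣ + c·sin δᵣ, so with known shifts a least-squares solve
per pixel gives φ = atan2(−c, b). When the shifts are unknown, the advanced
iterative algorithm (AIA) alternates that pixel step with a frame step that
re-estimates each δᵣ by least squares over pixels, until the shifts stop
changing. The phase converts to physical thickness through the optical path
length relation

&nbsp;&nbsp;&nbsp;&nbsp;φ(x,y) = p · (2π/λ) · Δn · h(x,y),

with λ the wavelength (660 nm by default), Δn = n₂ − n₁ the refractive-index
contrast between vesicle and medium (0.04 by default), and p the pass factor
(1 in transmission, 2 in reflection). Sizing then proceeds: remove the
background phase (reference subtraction, robust 2-D polynomial fit, or
median), convert to height, count particles by thresholded connected
components, take each particle's maximum height as its diameter (spherical
assumption), and histogram the diameters with number weights (1/N) or
intensity weights (∝ d⁶) for comparison with light-scattering instruments.

The package also contains the full forward model — spherical-cap thickness
profiles, phase maps, Gaussian diffraction blur of the complex field, fringe
synthesis with camera noise — so every analysis step is testable against
known ground truth, including the systematic *underestimation* of
sub-diffraction particles that blurring causes.

## Worked example

Simulate a field of ten immobilized vesicles (lognormal diameters around
250 nm) on a tilted background phase, acquire five phase-shifted frames with
1 count of camera noise, recover the phase with the AIA (shifts treated as
unknown), and size the particles:

```r
library(qpmsizer)

optics <- OpticalConfig(wavelengthNm = 660, deltaN = 0.04, pixelSizeNm = 86)
cfg <- ExperimentConfig(
  optics = optics,
  scene = list(n_particles = 10L,
               diameter = list(type = "lognormal", meanlog = log(250), sdlog = 0.25)),
  acquisition = list(noise_sigma = 1),
  retrieval = list(mode = "aia"),
  sizing = list(k_sigma = 4),
  seed = 101L)
res <- runEndToEnd(cfg)

res$report
#> RecoveryReport: true=10 detected=10 matched=10 falsePos=0
#>   diameter bias=-5.58 nm, RMSE=25.22 nm

head(res$particleTable[, c("particle_id", "x_px", "y_px", "max_phase_rad", "diameter_nm")], 4)
#>   particle_id     x_px      y_px max_phase_rad diameter_nm
#> 1           1 53.97602  42.01593    0.14239976    373.9498
#> 2           2 26.99070  22.02566    0.11242111    295.2242
#> 3           3  5.00750 115.00991    0.10413361    273.4608
#> 4           4 95.00506  43.01546    0.09899696    259.9716

res$distribution
#> SizeDistribution (number-weighted): n=10, mean=262.8 nm, mode=250.0 nm, sd=43.0 nm, PdI=0.027
```

All ten particles are recovered at their true positions with no false
positives. A maximum phase of 0.142 rad converts to
0.142 · 660 / (2π · 0.04) ≈ 374 nm of apex thickness, i.e. a 374 nm
diameter under the spherical assumption. The summary reports the weighted
mean, the modal histogram bin, the weighted standard deviation and the
polydispersity index PdI = (sd/mean)².

How sensitive is a size estimate to the assumed contrast? For a measured
apex phase of 0.12 rad:

```r
refractiveIndexSensitivity(0.12, optics, c(0.02, 0.04, 0.08))
#>   delta_n diameter_nm
#> 1    0.02    630.2536
#> 2    0.04    315.1268
#> 3    0.08    157.5634
```

Halving the assumed Δn doubles the diameter — choosing the contrast is the
dominant systematic in absolute sizing.

The same pipeline is scriptable from a shell (see
`inst/scripts/qpmsizer`): `simulate`, `retrieve`, `size`, `pipeline` and
`sensitivity` subcommands map 1:1 onto the package functions and exchange
self-describing TIFF/CSV/JSON artifacts.

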