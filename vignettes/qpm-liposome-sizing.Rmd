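---
title: "Sizing sub-diffraction vesicles from quantitative phase maps: models, choices and limits"
author: "qpmsizer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing sub-diffraction vesicles from quantitative phase maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpmsizer)
```

This vignette is the package's own account of the science it implements:
the imaging model, the retrieval algorithm and its failure modes, the
sizing procedure, what the synthetic data do and do not emulate, and the
numerical choices that were genuinely open.

## 1. The imaging model

A phase-shifting interferometric microscope records, per acquisition, M
fringe images of the same field,

$$I_r(x,y) = A(x,y) + B(x,y)\cos[\phi(x,y) + \delta_r], \qquad r = 1,\dots,M,$$

with background $A$, modulation $B$, specimen phase $\phi$ and per-frame
piston shifts $\delta_r$ introduced in the reference arm. $A$ and $B$ are
assumed constant across frames. The phase of an immobilized vesicle is the
optical path it adds:

$$\phi = p\,\frac{2\pi}{\lambda}\,\Delta n\, h,$$

where $h$ is the local thickness, $\Delta n = n_2 - n_1$ the
refractive-index contrast between vesicle and medium, $\lambda$ the vacuum
wavelength and $p$ the pass factor (1 in transmission; 2 in reflection,
where light traverses the specimen twice). For a sphere of diameter $d$
centered at in-plane distance $\rho$, the thickness is the chord
$2\sqrt{(d/2)^2-\rho^2}$, so the apex thickness equals $d$: this is the
entire basis of sub-diffraction sizing. Lateral size is diffraction-limited;
apex *phase* is not.

Defaults and units (nm for lengths, radians for phase, everywhere):

| parameter | default | meaning / why |
|---|---|---|
| `wavelengthNm` | 660 | imaging wavelength of the modeled instrument |
| `deltaN` | 0.04 | lipid vesicle vs aqueous medium; the standard assumed value |
| `passFactor` | 1 | the phase–height relation as written; reflection users set 2 |
| `pixelSizeNm` | 86 | object-plane sampling; comfortably Nyquist-samples a 500 nm PSF |
| `psfFwhmNm` | 0 | diffraction blur off unless requested |

The pass-factor question deserves a note: the height relation is stated in
single-pass form while the modeled instrument is a reflection microscope.
The package keeps $p = 1$ as the default and exposes $p = 2$ explicitly,
because the two conventions differ by an exact factor of 2 that the user
must own. Relatedly, the published worked example this pipeline descends
from (apex phases of 60 and 200 mrad read as 74 and 212 nm at
$\Delta n = 0.04$, $\lambda = 660$) is not reproducible from the relation
under either convention (single pass gives 158/525 nm, double pass
79/263 nm); the package does not attempt to match those printed values.

## 2. Forward simulation: what is emulated, what is not

`simulateScene()` composes, in order: integer-pixel random placement with a
minimum-separation constraint (rejection sampling, hard cap of 10\,000
attempts per particle), diameter sampling (point mass, lognormal, or
bimodal mixture — enough to emulate extrusion series), chord-law thickness,
the phase relation, an optional smooth background phase (tilt plus
curvature, emulating residual interferometer misalignment), Gaussian
diffraction blur, and fringe synthesis with additive Gaussian camera noise.

Choices worth defending:

* **Blur acts on the complex field** $e^{i\phi}$, not on $\phi$ directly,
  because diffraction propagates fields, not phases. For the milliradian
  phases of vesicles the two nearly coincide, but the field convention is
  the physically defensible one. The kernel is a normalized Gaussian of
  stated FWHM — separable, exactly testable against a brute-force
  convolution, and a good stand-in for an Airy core; it has no negative
  lobes, so it cannot create ringing artifacts the detector would then
  count. Convolution uses replicate boundaries: a tilted background phase
  must not wrap across image edges (circular boundaries manufacture strong
  spurious edge structures — this was caught by simulation).
* **Overlapping particles add** their thicknesses (thin-specimen
  additivity), consistent with the linearity of optical path in $h$.
* **Noise is additive Gaussian**, unclipped in floating point; clipping to
  $[0, 65535]$ and quantization happen only on 16-bit TIFF export.
* **Placement is on integer pixel centers**, so a particle's apex falls
  exactly on a sample and the noiseless, unblurred chain recovers diameters
  to rounding. Real acquisitions have subpixel centers; the resulting apex
  undersampling error (bounded by the chord drop across half a pixel) is
  *not* emulated by default, which is one reason passing tests here do not
  certify real-data accuracy.

Not modeled at all: physical-optics propagation (defocus, aberrations,
angular spectrum), partial coherence and speckle, fluorescence, camera
nonlinearity, drift between frames. The synthetic fields certify the
*computational* pipeline, not the instrument.

## 3. Phase retrieval

With known shifts, substituting $a = A$, $b = B\cos\phi$, $c = -B\sin\phi$
linearizes the fringe model to $I_r = a + b\cos\delta_r + c\sin\delta_r$;
the $3\times 3$ normal matrix depends only on the shifts, so one
factorization serves all pixels, and $\phi = \mathrm{atan2}(-c, b)$,
$\hat B = \sqrt{b^2+c^2}$. At least 3 frames are required; shift sets
congruent modulo $\pi$ are singular and rejected by name.

With unknown shifts, `aiaRetrieve()` alternates this pixel step with a
frame step (per frame, least squares over pixels of
$I_r = a' + b'\cos\phi + c'\sin\phi$, giving
$\delta_r = \mathrm{atan2}(-c', b')$) until the largest shift change falls
below `tolRad` ($10^{-6}$ by default, at most 100 alternations;
non-convergence is a reported flag, never an error). The joint problem is
invariant under a global phase piston (absorbed by anchoring
$\delta_1 = 0$) and under the sign flip
$(\phi,\delta) \to (-\phi,-\delta)$; results are defined up to these, and
the pipeline orients the sign so particles are positive bumps (positive
skew of the background-removed field).

Two genuine failure modes, found and characterized during development:

* **Three-frame spurious fixed points.** With $M = 3$ the pixel step
  interpolates the data exactly for *any* non-degenerate shift triple, so
  the alternation acquires attractors that are not the true solution; only
  the frame-step residual distinguishes them (zero at truth, far from zero
  at the impostors). For $M = 3$ the package therefore restarts the
  iteration from a deterministic grid of shift triples and returns the
  candidate with the smallest frame-step residual. With $M \ge 4$ the
  equally spaced initialization has proven reliable.
* **Small-span phase is hostile territory.** The frame-step regressors
  $\{1, \cos\phi, \sin\phi\}$ become collinear as the phase range shrinks
  (for a field of milliradian-scale vesicles on a flat background, the
  design is numerically rank-2). Two consequences. First, AIA benchmarks
  here use smooth random phases spanning nearly the full principal range
  (peak 3 rad) — the regime the alternation is designed for; with spans of
  ~4 rad a minority of three-frame cases converge to a wrong attractor
  from *every* initialization. Second, and practically: real nanoparticle
  fields get their span from the background tilt of the interferometer,
  which is precisely why the numerical background-removal step exists.
  Pipelines over near-flat fields should treat the shifts as known (or
  calibrated) rather than self-calibrated; `retrieval$mode` exposes both.

Background removal supports reference-frame subtraction, scalar median
subtraction, and the default: a least-squares 2-D polynomial surface
(total degree 2 by default — slow illumination curvature without eating
particle signal), refit once after excluding pixels more than 3 robust
sigma *above* the first fit, because particles are positive outliers.
Robust sigma is $1.4826 \times$ MAD throughout the package. No phase
unwrapping is performed anywhere: vesicle phases are far below $\pi$, and a
wrap-risk warning fires if more than 0.1% of pixels sit within 0.1 rad of
$\pm\pi$.

## 4. Detection and sizing

Detection thresholds the background-removed map at
$\mathrm{median} + k\sigma_{\mathrm{robust}}$ with $k = 3$ by default, an
absolute floor of `minPhaseRad` = 0.2 mrad above the median, connected
components at 8-connectivity, and a minimum area of 2 px. The floor
represents the instrument's phase sensitivity; without it, a noiseless
simulated map has robust sigma at rounding level ($\sim 10^{-19}$) and the
threshold collapses onto numerical dust. Its value sits well below the
faintest structure of interest modeled here (a 100 nm sphere under 500 nm
blur retains a ~0.7 mrad apex). Each surviving component yields one record:
phase-weighted centroid (0-based pixel coordinates, x = column, y = row),
area, maximum phase; records are sorted by descending maximum phase with
stable ids. The diameter estimate is the height conversion of the
component's maximum phase — deliberately the plain maximum, not a fitted
apex, matching the procedure this pipeline models.

Two parameter regimes are used deliberately in the validation experiments:

* **Noiseless, unblurred validation scenes** use `min_area_px = 1`: a
  100 nm sphere genuinely occupies a single 86 nm pixel, and discarding
  singletons there is geometrically wrong. The default of 2 px is for
  realistic (blurred and/or noisy) data where singletons are noise.
* **Detection at the noise limit** uses matched-filter pre-smoothing
  (`smooth_fwhm_nm`, default off): Gaussian smoothing at the PSF scale
  before thresholding, with the maximum phase then read from the smoothed
  map. For a particle of volume $V$ imaged with PSF width
  $\sigma_{\mathrm{psf}}$, pixel size $p$ and per-pixel phase noise
  $\sigma_\phi$, the matched-filter detection SNR is approximately
  $$\mathrm{SNR} \approx \frac{(2\pi \Delta n/\lambda)\, V}
  {2\sqrt{\pi}\,\sigma_{\mathrm{psf}}\,\sigma_\phi\, p}.$$
  The formula makes the design trade explicit: at the default 86 nm
  sampling, a 100 nm vesicle under a 250 nm-FWHM PSF and 1% camera noise
  sits at SNR $\approx 1$ — undetectable — while oversampling at 20 nm
  pixels lifts it to $\approx 4$. The size-ordering experiment below was
  designed from this formula, not tuned afterward.

Distributions support number weighting ($1/N$) and intensity weighting
($w_i \propto d_i^6$, computed on diameters scaled by their maximum to
avoid overflow), a histogram over $[0, d_{\max}]$ at 20 nm bin width, and a
summary with weighted mean, modal bin center, weighted population SD, and
PdI $= (\sigma/\mu)^2$. The cumulants PdI of light-scattering instruments
is not computable from single-particle data in exact correspondence, so the
squared coefficient of variation is reported under both weightings and
comparisons with instrument PdI should stay qualitative.

## 5. The validation experiments and their problem sizes

The test suite and `scripts/acceptance.R` run these seeded studies (sizes
chosen to exercise the contracts at realistic scale):

* closed-form equivalence: 20 quarter-wave 4-frame stacks, 128×128;
* AIA recovery: 20 noiseless stacks, M ∈ {3,4,5}, random non-degenerate
  shifts, 64×64, full-span smooth phases, up to 300 alternations (the
  three-frame alternation converges linearly and can need a few hundred);
* round trip: 18-point grid over wavelength, contrast and pass factor;
* sizing recovery: 10-particle scenes at 100/200/400/660 nm, noiseless and
  unblurred — exact counts, bias at rounding level;
* underestimation: 20 seeds, 100 nm particles under 500 nm blur — the mean
  estimate collapses to a few nanometres, never above 100 (the
  high-frequency loss that makes sub-diffraction sizing biased low);
* weighting: the {100, 200} nm pair gives exactly 1:64 weights; on 100
  random polydisperse sets the intensity-weighted mean never falls below
  the number-weighted mean;
* discrimination: 20-particle scenes at 100 vs 200 nm, 250 nm blur, 1%
  noise, AIA retrieval over a tilted background, 20 nm pixels with 250 nm
  matched-filter smoothing, $k = 4$ (on a smoothed field the effective
  number of independent samples drops, so 3$\sigma$ is permissive),
  minimum area 25 px. Both classes are *severely* underestimated (means
  ~10 and ~24 nm) — yet strictly ordered in every seed, which is the
  scientific claim: size ordering below the diffraction limit survives
  blur and noise even where absolute sizing does not.
* determinism: an identical config and seed reproduces every CSV/JSON byte.

## 6. Known limitations

* Absolute sizes under blur are biased low by design of the physics, not
  corrected; deconvolution or PSF-model apex fitting is out of scope.
* The assumed $\Delta n$ enters the diameter inversely;
  `refractiveIndexSensitivity()` quantifies that, but choosing $\Delta n$
  for real vesicles remains the dominant systematic.
* AIA self-calibration needs phase span; near-flat fields require known
  shifts (Section 3).
* Subpixel particle centers, aberrated PSFs and frame-to-frame drift are
  not emulated; conclusions from the synthetic suite transfer to real data
  only insofar as those effects are small.
* 32-bit float TIFF storage quantizes doubles; write–read–write round
  trips are bit-stable from the first readback onward.
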