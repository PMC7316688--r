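---
title: "Light-source calibration from specular highlights: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Light-source calibration from specular highlights: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speclight)
```

## The problem

Functional multispectral imaging in open surgery estimates tissue parameters
— above all hemoglobin oxygenation — from per-pixel band spectra. The
regressors that perform this inversion are trained on measurements rendered
under a *known* illuminant; when operating-room lighting changes (overhead
lights, head torches, endoscopic sources being moved and mixed), the
deployed illuminant no longer matches the training illuminant and the
estimates degrade badly. `speclight` implements an automatic light-source
calibration that recovers the current illuminant spectrum from the specular
highlights of dedicated low-exposure images, plus everything needed to
validate it in silico: four classical baseline estimators, a layered-tissue
image formation model, a dichromatic scene simulator, and the downstream
oxygenation-regression experiment that quantifies the clinical benefit of
calibrating.

## The dichromatic model and the calibration method

Reflected light at pixel $(i,j)$ in band $k$ splits into a diffuse and a
specular part,

$$ (I_k)_{(i,j)} = (S_k)_{(i,j)} L_k + c \cdot L_k, $$

where $S_k$ is the surface (tissue) reflectance, $L_k$ the illuminant in
band $k$, and $c$ a spectrally flat specular coefficient
(neutral-interface assumption). In a pixel dominated by the specular term
the measured band vector is simply a scaled copy of the illuminant — so
specular highlights are natural, label-free illuminant probes. At standard
exposures, however, highlights saturate the detector; the method therefore
uses *low-exposure* calibration images, in which highlight pixels are bright
but still valid.

The pipeline (`calibrate()`):

1. **Valid-pixel mask.** A pixel is valid iff every band lies strictly
   inside $(I_{min}, I_{max})$. $I_{max} = 950$ counts guards the sensor's
   nonlinear range near the 10-bit ceiling; $I_{min}$ is set per exposure
   from dark-frame statistics as mean dark lightness $+ 3$ sd. Requiring
   *all* bands in range is the strictest reading; it keeps partially
   saturated spectra out of the estimate.
2. **Highlight selection.** Lightness is the band-mean per pixel; the
   $N_P = 100$ brightest valid pixels are selected (all of them when fewer
   exist — robustness was reported for $N_P$ between 75 and 200, so
   clamping beats failing). Ties break deterministically: lightness
   descending, then row, then column ascending.
3. **Estimation.** Each selected pixel spectrum is dark-corrected (the
   scalar mean dark level subtracted per band, clamped at zero),
   L1-normalized, and the estimate is the mean of these unit-mass spectra,
   re-normalized. The dark correction is the one extension over the plain
   normalize-and-average rule: a flat dark offset of ~20 counts otherwise
   biases every estimate by a few tenths of a degree and puts exact
   recovery out of reach even in noise-free conditions.
4. **Exposure selection.** Over a bracketed series (5–150 ms in 5 ms
   steps) the goodness metric
   $G(T_{exp}) = \mathrm{median}\big((I_L - \bar{D})/\bar{D}\big)$
   over the selected pixels is computed per exposure, with $\bar{D}$ the
   mean dark lightness at that exposure; the exposure with maximal $G$
   wins, ties going to the shorter exposure. Exposures with no valid
   highlight pixel get $G = -\infty$.

Spectra are compared by the **angular error** — the Euclidean angle between
spectra as vectors, in degrees — which is invariant to the overall
intensity scale, the natural property when only the spectral *shape*
matters.

## Baseline estimators

`max_rgb()`, `gray_world()`, `shades_of_gray()` and `gray_edge()` extend
the four standard single-image color-constancy estimators to multispectral
cubes: per-band maximum, mean, Minkowski mean of order $p$ (default 6), and
Minkowski-pooled Gaussian-smoothed gradient magnitude ($\sigma = 2$ px by
default; the source literature leaves $\sigma$ open). Gradients use central
differences on the smoothed band with reflection padding; border pixels are
excluded from the pooling to avoid padding artifacts. All four accept the
same valid-pixel mask as the main method for like-for-like comparisons, but
default to the whole image, the convention in the color-constancy
literature. Their known failure mode on surgical scenes — tissue is
emphatically not achromatic on average — is exactly what the comparison
experiment measures.

## Tissue forward model

Tissue samples are 3-layer property vectors: per layer a thickness
(20–2000 µm), blood volume fraction (0–30%) and hemoglobin oxygenation
(0–100%), plus shared reduced-scattering amplitude at 500 nm (5–50 cm⁻¹),
scattering power (0.5–2.5) and flat background absorption (0–1 cm⁻¹), all
sampled uniformly. Absorption mixes the whole-blood endmembers linearly:
$\mu_a = \mathrm{bvf}\,(\mathrm{sox}\,\mu_a^{oxy} + (1-\mathrm{sox})\,\mu_a^{deoxy}) + \mu_a^{bg}$.
The packaged endmember table is a *synthetic* Gaussian-mixture
approximation of whole-blood absorption (Soret tail, 542/577 nm oxygenated
double peak, 555 nm deoxygenated peak, deoxygenated-dominant red gap) at
150 g/L hemoglobin; a two-Gaussian pseudo-hemoglobin mode exists for tests
that must not depend on the fixture.

Converting properties to reflectance uses a deterministic closed-form
layered model rather than photon-transport Monte Carlo: per wavelength each
layer's semi-infinite diffuse reflectance is a fixed monotone map of its
reduced albedo $a' = \mu_s'/(\mu_a + \mu_s')$,

$$ R_\infty(a') = r_{max}\, a'\, e^{-k(1-a')/(1+a')}, \quad k = 6,\; r_{max} = 0.85, $$

and finite layers combine top-down through their two-pass transmission
$T_l = e^{-2(\mu_a + \mu_s') d_l}$ as
$R_l = (1-T_l) R_\infty(a'_l) + T_l R_{l+1}$, bottom layer semi-infinite.
This choice trades radiative-transfer fidelity for determinism and speed;
the calibration method under test depends only on the dichromatic
structure of the *scene*, not on the exact shape of diffuse tissue spectra,
and the map is fixed and documented so every result is reproducible. With
zero absorption the model returns the constant $r_{max}$ — a useful exact
test point.

Camera bands integrate the spectral radiance by the trapezoidal rule:
$I_k = \alpha\, w_k \int \xi_k(\lambda) L(\lambda) r(\lambda)\,d\lambda$,
with $\xi_k$ 16 Gaussian responses (centers evenly spaced 465–630 nm, FWHM
15 nm — the real mosaic sensor's responses are unpublished, so a generic
narrow-band bank is used), $\alpha$ a multiplicative gain and $w_k$
i.i.d. multiplicative band noise $\mathcal{N}(1, \sigma_w)$ truncated at
zero (shot noise in the large-intensity approximation), $\sigma_w = 0.1$ by
default. The wavelength grid is 450–720 nm at 2 nm.

## Scene simulator: what it emulates, and what it does not

`dichromatic_scene()` renders 128×128-pixel scenes with three
nearest-center tissue regions, a per-pixel gain field
$\alpha \in [0.7, 1.3]$, and two specular populations whose scales were set
so the simulator reproduces the qualitative behaviour reported for real
surgical recordings — saturated highlight cores with valid rims at
standard exposures, usable highlight pixels at low exposure, goodness
peaking at low exposure:

* **Highlight blobs** (12 per scene): super-Gaussian profiles (order 2,
  radius 2–5 px) with peak specular-to-diffuse contrast log-uniform in
  [8, 45] — true glare, which exceeds body reflection many-fold by nature.
  The flat-core/sharp-rim profile matters: once a core saturates, few
  near-ceiling rim pixels remain, so $G$ genuinely drops at long exposures
  instead of riding the rim continuum.
* **Sheen patches** (3 per scene): broad (8–16 px), faint (contrast
  1.5–4) gloss, the wet-tissue shine that keeps *some* specular signal
  valid at long exposures — without it the fixed-exposure comparison at
  60 ms would have no specular pixels at all.

The mean diffuse tissue signal is 100 ADC counts at the 40 ms reference
exposure (dark organs reflect weakly relative to glare). Rendering scales
the analog signal linearly with exposure, adds dark counts
(20 + 1·$T_{exp}$ counts; an appreciable dark *rate* is what makes the
goodness metric's normalization by $\bar{D}(T_{exp})$ informative), adds
2-count Gaussian read noise, quantizes to integers and clips to the 10-bit
range. Dark statistics are computed from rendered dark frames, mirroring
the physical lights-off procedure, not from the closed-form dark model.

Camera poses are emulated by re-randomizing highlight geometry, gain field
and tissue draw per scene; there is no 3-D geometry, shading or shadowing.
Noise-free validation scenes additionally zero the diffuse term under
highlight blobs (glare fully occluding body reflection), the idealized
configuration in which recovery is exact up to quantization. Passing tests
on this simulator therefore demonstrate correctness of the *method* under
the dichromatic model and robustness to sensor noise, quantization,
saturation and dark current — not fidelity to any particular tissue type,
camera, or the radiometric detail of real operating rooms.

## Synthetic illuminant set

`reference_illuminants()` provides five smooth L1-normalized spectra
emulating common OR sources: two near-identical xenon-like spectra, a
halogen slope (3200 K blackbody shape), a triphosphor fluorescent on a weak
continuum, and a blue-pumped phosphor LED. The shapes were fixed, before
any accuracy experiment, so that their pairwise angular errors *in camera
band space* span roughly 1–26 degrees — the spread characteristic of mixed
OR lighting — giving the mismatch experiment both a nearly
indistinguishable pair and strongly separated pairs.

## Oxygenation experiment

One pool of 15,000 tissue samples is split 10,000/5,000. Per illuminant a
training and a test set are rendered from the *same* samples (identical
labels, different measurements); measurement vectors are L1-normalized, so
the per-sample gain cancels — spectra are compared by shape only. The
regression target is the first-layer oxygenation: the superficial layer
dominates reflectance in the layered model, and which depth-aggregate a
16-band measurement could identify is ill-posed anyway; the choice is
configurable. The regressor is a random forest (`ranger`, 200 trees,
minimum node size 5, single-threaded for determinism, predictions clipped
to [0, 1]); the hyperparameters are fixed package defaults since nothing
in the problem constrains them tightly, and the experiment's conclusions
are insensitive to them.

Three conditions are evaluated per test illuminant: **matched** (train and
test under the same illuminant), **mismatched** (each of the other
illuminants), and **calibrated** (a regressor trained under a calibration
*estimate* of that illuminant, one per validation scene). Calibration
estimates live in 16-band camera space but training needs a spectrum on
the wavelength grid; `illuminant_from_bands()` divides band values by the
response integrals (narrow-band approximation), interpolates through the
band centers with a natural spline, clamps at zero and renormalizes. The
summary reports $(1 - \mathrm{MAE}_{cal}/\mathrm{MAE}_{mis}) \times 100\%$
per test illuminant.

The scaled-down default (`n_train = 2000`, `n_test = 500`) keeps
exploratory runs interactive; the full-scale study sizes above are used by
`scripts/acceptance.R` and the validation tests.

## Numerical and degenerate-input conventions

* Angles are reported in degrees only; the arccosine argument is clamped
  to $[-1, 1]$.
* All estimator outputs are L1-normalized; zero vectors, empty masks and
  empty selections raise classed errors (`speclight_error_*`) rather than
  returning garbage.
* Exposure and bank-selection ties break deterministically (shorter
  exposure; lexicographically smaller id).
* Minkowski pooling rescales each band by its own maximum before raising
  to the power $p$, so large $p$ cannot underflow a band.
* Cubes are integer ADC counts in `[0, adc_max]`; storage is lossless
  (16-bit TIFF pages or ENVI uint16 + JSON sidecar).
* Every stochastic stage takes an explicit seed; derived child seeds keep
  parallel stages independent but reproducible.

## Known limitations

* The diffuse reflectance stand-in is not radiative transfer; absolute
  oxygenation errors transfer to real tissue only in order of magnitude.
* A single scene-wide illuminant is assumed; patch-wise or multi-illuminant
  estimation is out of scope.
* The regressor bank adapts by selecting among discretely many pre-trained
  regressors (`select_regressor()`), not by continuously adapting one
  model.
* Baseline comparisons at fixed exposures depend on how much faint gloss a
  scene offers; the packaged defaults encode one plausible surgical
  phenomenology.

## A worked example

```{r example, eval = FALSE}
camera <- camera_model()
lights <- reference_illuminants(camera$grid)

scene <- dichromatic_scene(lights$ls2, camera, seed = 11)
series <- generate_exposure_series(scene, seed = 12)
cal <- calibrate(series)
glance(cal)

truth <- band_integrate(rep(1, length(camera$grid)), lights$ls2, camera)
angular_error(cal$estimate, as.numeric(truth))

autoplot(cal)          # goodness profile with the chosen exposure
autoplot(cal$estimate) # the recovered spectrum
```
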