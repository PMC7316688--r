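# speclight

Light-source calibration for multispectral imaging via specular-highlight
analysis — with the simulation framework to validate it and quantify its
downstream benefit for tissue oxygenation estimation.

## The problem

Multispectral imaging can estimate functional tissue parameters — notably
hemoglobin oxygenation — live during surgery, but the regressors doing the
inversion are trained under a *known* illuminant. In open surgery the
lighting mix changes constantly, and a mismatch between the deployed and
training illuminants corrupts the estimates. `speclight` recovers the
current illuminant spectrum automatically from dedicated low-exposure
images: specular highlights reflect a scaled copy of the illuminant
(dichromatic reflection model, `I_k = S_k·L_k + c·L_k`), and at low
exposure those highlight pixels are bright yet unsaturated, so their
normalized spectra *are* illuminant estimates.

The method: mask valid pixels (every band strictly inside
`(I_min, I_max)`, with `I_min` from dark statistics and `I_max = 950`),
select the `N_P = 100` brightest valid pixels by lightness (band mean),
dark-correct and L1-normalize their spectra, and average. The calibration
exposure is chosen automatically over a 5–150 ms sweep by maximizing the
goodness metric

```
G(T_exp) = median over highlight pixels of (I_L − D̄(T_exp)) / D̄(T_exp)
```

where `D̄` is the mean dark-frame lightness. Spectra are compared by
angular error (the angle between spectra as vectors, in degrees —
scale-invariant). Four classical baselines (max-band, gray-world,
shades-of-gray with Minkowski order `p = 6`, gray-edge) are included for
comparison, and a layered-tissue + dichromatic-scene simulator provides
ground truth for validation and for the illuminant-mismatch oxygenation
experiment.

## A worked example

```r
library(speclight)

camera <- camera_model()                     # 16 Gaussian bands, 465-630 nm
lights <- reference_illuminants(camera$grid) # 5 synthetic OR light sources

scene  <- dichromatic_scene(lights$ls2, camera, seed = 11)  # halogen-lit tissue
series <- generate_exposure_series(scene, seed = 12)        # 5-150 ms sweep
cal    <- calibrate(series)

glance(cal)
#> # A tibble: 1 × 5
#>   exposure_ms goodness n_highlight_pixels n_valid_pixels n_exposures
#>         <dbl>    <dbl>              <int>          <int>       <int>
#> 1          10     16.8                100           9077          30

truth <- band_integrate(rep(1, length(camera$grid)), lights$ls2, camera)
angular_error(cal$estimate, as.numeric(truth))
#> [1] 1.686979
```

The calibration picked a 10 ms exposure (highlights bright but below the
sensor's nonlinear range) and recovered the halogen spectrum to 1.7° —
under the multiplicative band noise (sd 0.1), dark current, read noise and
10-bit quantization the simulator applies. `autoplot(cal)` shows the
goodness profile with the chosen exposure; `autoplot(cal$estimate)` the
recovered spectrum; `tidy(cal)` returns it as a tibble.

The five packaged illuminants span band-space angular errors from 1.0°
(the two xenon-like sources) to 26.4° (fluorescent vs LED):

```r
round(illuminant_distance_matrix(lights, camera), 1)
#>      ls1  ls2  ls3  ls4  ls5
#> ls1  0.0 17.2 22.3  1.0 13.4
#> ls2 17.2  0.0 25.1 16.2 19.1
#> ls3 22.3 25.1  0.0 22.2 26.4
#> ls4  1.0 16.2 22.2  0.0 13.2
#> ls5 13.4 19.1 26.4 13.2  0.0
```

Downstream, `run_illuminant_mismatch_experiment()` trains a
random-forest oxygenation regressor per illuminant (and per calibration
estimate), evaluating matched / mismatched / calibrated conditions; see
the vignette (`vignettes/light-source-calibration.Rmd`) for the models,
parameter choices and their rationale. A thin command-line surface over
the same functions ships at `inst/cli/speclight.R`
(`Rscript speclight.R` prints the subcommands).

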