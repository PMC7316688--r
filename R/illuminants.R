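#' Synthetic reference illuminant set
#'
#' Five smooth relative-irradiance spectra on the wavelength grid, emulating
#' common operating-room light sources: two near-identical xenon-like spectra
#' (nearly flat; `ls1`, `ls4`), a warm halogen-like slope (`ls2`, ~3200 K
#' blackbody shape), a spiky triphosphor fluorescent (`ls3`) and a blue-pumped
#' phosphor LED (`ls5`). The set is constructed so that pairwise angular
#' errors *in camera band space* span roughly 1-26 degrees, the spread typical
#' of mixed OR lighting.
#'
#' @param grid A [wavelength_grid()].
#' @return Named list of L1-normalized numeric vectors on `grid`.
#' @export
reference_illuminants <- function(grid = wavelength_grid()) {
  bb <- function(t_kelvin) {
    l <- grid * 1e-9
    (1 / l^5) / (exp(0.0143877688 / (l * t_kelvin)) - 1)
  }
  g <- function(mu, s) exp(-((grid - mu) / s)^2)
  spectra <- list(
    # xenon-like: broad, gently humped around the mid-visible
    ls1 = 1 + 0.15 * g(520, 120),
    # halogen: rising strongly toward the red (approx. 3200 K blackbody)
    ls2 = bb(3200),
    # fluorescent: triphosphor peaks on a weak continuum
    ls3 = 0.5 + 1.0 * g(487, 10) + 1.7 * g(546, 9) + 1.45 * g(611, 10),
    # second xenon from another maker: small spectral tilt vs ls1
    ls4 = (1 + 0.15 * g(520, 120)) * (1 + 3.4e-4 * (grid - 585)),
    # LED: blue pump + broad phosphor
    ls5 = 0.3 + 0.85 * g(465, 16) + 0.7 * g(575, 60)
  )
  lapply(spectra, l1_normalize)
}

#' Band-space distance matrix of an illuminant set
#'
#' Renders each illuminant to camera bands (flat unit reflectance) and
#' returns the pairwise angular errors in degrees.
#'
#' @param illuminants Named list of spectra on the camera grid.
#' @param camera A [camera_model()].
#' @return Symmetric matrix of angles (degrees).
#' @export
illuminant_distance_matrix <- function(illuminants, camera) {
  bands <- lapply(illuminants, function(L) {
    as.numeric(band_integrate(rep(1, length(camera$grid)), L, camera))
  })
  n <- length(bands)
  m <- matrix(0, n, n, dimnames = list(names(illuminants), names(illuminants)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) m[i, j] <- angular_error(bands[[i]], bands[[j]])
  }
  m
}

#' Convert a band-space illuminant estimate to a spectrum on the grid
#'
#' Calibration estimates live in camera band space; rendering training data
#' under an estimated illuminant needs a spectrum on the wavelength grid.
#' Each band value is divided by its response curve's integral (narrow-band
#' approximation `B_k ~ L(c_k) * integral(xi_k)`), the resulting samples at
#' the band centers are interpolated with a natural spline, clamped at 0 and
#' L1-normalized.
#'
#' @param bands Band-space estimate (length `camera$n_bands`).
#' @param camera A [camera_model()].
#' @return L1-normalized spectrum on `camera$grid`.
#' @export
illuminant_from_bands <- function(bands, camera) {
  if (length(bands) != camera$n_bands) stop_dimension("One value per band required.")
  w <- trapezoid_weights(camera$grid)
  norm <- as.numeric(camera$response %*% w)
  at_centers <- as.numeric(bands) / norm
  sp <- spline(camera$centers, at_centers, xout = camera$grid, method = "natural")$y
  # constant extrapolation outside the band-center range
  sp[camera$grid < min(camera$centers)] <- at_centers[which.min(camera$centers)]
  sp[camera$grid > max(camera$centers)] <- at_centers[which.max(camera$centers)]
  l1_normalize(pmax(sp, 0))
}
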