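#' Wavelength grid
#'
#' @param from,to,by Grid limits and spacing in nm (default 450-720 nm at
#'   2 nm, the visible range the default camera covers).
#' @return Strictly increasing numeric vector of wavelengths.
#' @export
wavelength_grid <- function(from = 450, to = 720, by = 2) {
  g <- seq(from, to, by = by)
  if (length(g) < 2 || any(diff(g) <= 0)) stop_config("Grid must be strictly increasing.")
  g
}

#' Whole-blood absorption table
#'
#' Per-wavelength absorption coefficients (1/cm) of fully oxygenated and
#' fully deoxygenated whole blood, interpolated onto `grid`.
#'
#' `source = "tabulated"` reads the packaged table
#' `synthetic_whole_blood_mua.csv`, a synthetic Gaussian-mixture
#' approximation of the whole-blood absorption curves (Soret tail, the
#' oxygenated 542/577 nm double peak, the deoxygenated 555 nm peak and the
#' deoxygenated-dominant red gap beyond 600 nm) at 150 g/L hemoglobin.
#' `source = "pseudo"` builds a fully synthetic two-Gaussian pseudo-hemoglobin
#' pair in code, for tests that must not depend on the fixture file.
#'
#' @param grid A [wavelength_grid()].
#' @param source `"tabulated"` or `"pseudo"`.
#' @return Tibble of class `chromophore_table` with columns `wavelength_nm`,
#'   `mua_oxy`, `mua_deoxy` (1/cm), one row per grid point.
#' @export
chromophore_table <- function(grid = wavelength_grid(), source = c("tabulated", "pseudo")) {
  source <- match.arg(source)
  if (source == "tabulated") {
    path <- system.file("extdata", "synthetic_whole_blood_mua.csv", package = "speclight")
    if (!nzchar(path)) stop_not_found("Packaged chromophore table not found.")
    raw <- read.csv(path)
    if (min(grid) < min(raw$wavelength_nm) || max(grid) > max(raw$wavelength_nm)) {
      stop_config("Grid extends beyond the packaged chromophore table.")
    }
    oxy <- approx(raw$wavelength_nm, raw$mua_oxy, xout = grid)$y
    deoxy <- approx(raw$wavelength_nm, raw$mua_deoxy, xout = grid)$y
  } else {
    oxy <- 60 * exp(-((grid - 560) / 30)^2) + 0.5
    deoxy <- 80 * exp(-((grid - 600) / 40)^2) + 0.5
  }
  if (any(oxy <= 0) || any(deoxy <= 0)) stop_format("Absorption must be > 0.")
  out <- tibble::tibble(wavelength_nm = grid, mua_oxy = oxy, mua_deoxy = deoxy)
  class(out) <- c("chromophore_table", class(out))
  out
}

#' Default tissue-parameter ranges
#'
#' Uniform sampling ranges for the three-layer tissue model: per layer the
#' thickness (20-2000 um), blood volume fraction (0-30%) and hemoglobin
#' oxygenation (0-100%); shared across layers the reduced-scattering
#' amplitude at 500 nm, the scattering power of the `(lambda/500)^-b` decay,
#' and a flat background absorption.
#'
#' @return Named list of `c(min, max)` ranges.
#' @export
tissue_ranges <- function() {
  list(
    thickness_um = c(20, 2000),
    bvf = c(0, 0.3),
    sox = c(0, 1),
    mus500 = c(5, 50),        # reduced scattering at 500 nm, 1/cm
    scatter_power = c(0.5, 2.5),
    mua_background = c(0, 1)  # 1/cm
  )
}

#' Draw tissue property samples
#'
#' Independent uniform draws of the layered tissue property vector; columns
#' `thickness_um_1..3`, `bvf_1..3`, `sox_1..3` (per layer, superficial first)
#' plus shared `mus500`, `scatter_power`, `mua_background`.
#'
#' @param n Number of samples.
#' @param seed Optional RNG seed for reproducibility.
#' @param ranges Ranges as from [tissue_ranges()].
#' @return Tibble of class `tissue_samples` with one row per sample.
#' @export
sample_tissue <- function(n, seed = NULL, ranges = tissue_ranges()) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop_config("`n` must be >= 1.")
  for (r in ranges) {
    if (length(r) != 2 || r[1] > r[2]) stop_config("Each range must be c(min, max).")
  }
  with_seed(seed, {
    u <- function(r) runif(n, r[1], r[2])
    out <- tibble::tibble(
      thickness_um_1 = u(ranges$thickness_um),
      thickness_um_2 = u(ranges$thickness_um),
      thickness_um_3 = u(ranges$thickness_um),
      bvf_1 = u(ranges$bvf), bvf_2 = u(ranges$bvf), bvf_3 = u(ranges$bvf),
      sox_1 = u(ranges$sox), sox_2 = u(ranges$sox), sox_3 = u(ranges$sox),
      mus500 = u(ranges$mus500),
      scatter_power = u(ranges$scatter_power),
      mua_background = u(ranges$mua_background)
    )
    class(out) <- c("tissue_samples", class(out))
    out
  })
}

#' Absorption coefficient of perfused tissue
#'
#' `mua(lambda) = bvf * (sox * mua_oxy + (1 - sox) * mua_deoxy) + background`,
#' linear in both the blood volume fraction and the oxygenation.
#'
#' @param bvf Blood volume fraction in `[0, 0.3]` (recycled).
#' @param sox Oxygenation in `[0, 1]` (recycled).
#' @param wavelength Wavelengths (nm) within the table's grid.
#' @param table A [chromophore_table()].
#' @param background Flat background absorption (1/cm), default 0.
#' @return Absorption coefficient(s) in 1/cm.
#' @export
absorption_coefficient <- function(bvf, sox, wavelength, table, background = 0) {
  if (any(bvf < 0 | bvf > 0.3 + 1e-12) || any(sox < 0 | sox > 1 + 1e-12)) {
    stop_config("bvf must lie in [0, 0.3] and sox in [0, 1].")
  }
  oxy <- approx(table$wavelength_nm, table$mua_oxy, xout = wavelength)$y
  deoxy <- approx(table$wavelength_nm, table$mua_deoxy, xout = wavelength)$y
  if (anyNA(oxy) || anyNA(deoxy)) stop_config("Wavelength outside table coverage.")
  bvf * (sox * oxy + (1 - sox) * deoxy) + background
}

# Semi-infinite diffuse reflectance as a monotone map of the reduced albedo
# a' = mus' / (mua + mus'): R_inf(a') = r_max * a' * exp(-k (1-a')/(1+a')),
# k = 6, r_max = 0.85. R_inf(0) = 0, R_inf(1) = r_max.
r_infinity <- function(albedo, k = 6, r_max = 0.85) {
  r_max * albedo * exp(-k * (1 - albedo) / (1 + albedo))
}

#' Reflectance spectra of layered tissue samples
#'
#' Deterministic closed-form layered diffuse-reflectance model. Per
#' wavelength, each layer's semi-infinite reflectance `R_inf(a')` is computed
#' from its reduced albedo; finite thickness enters through the two-pass
#' transmission `T = exp(-2 (mua + mus') d)`, combining layers top-down as
#' `R_l = (1 - T_l) R_inf(a'_l) + T_l R_(l+1)` with a semi-infinite bottom
#' layer. With zero absorption everywhere this yields the constant `r_max`.
#'
#' @param samples A [sample_tissue()] tibble (or single-row data frame).
#' @param grid A [wavelength_grid()].
#' @param table A [chromophore_table()] covering the grid.
#' @return Numeric matrix `n_samples x n_wavelengths` of reflectance in
#'   `[0, 1]`.
#' @export
reflectance_spectrum <- function(samples, grid = wavelength_grid(),
                                 table = chromophore_table(grid)) {
  samples <- tibble::as_tibble(samples)
  n <- nrow(samples)
  oxy <- approx(table$wavelength_nm, table$mua_oxy, xout = grid)$y
  deoxy <- approx(table$wavelength_nm, table$mua_deoxy, xout = grid)$y
  if (anyNA(oxy) || anyNA(deoxy)) stop_config("Grid outside table coverage.")
  # reduced scattering, shared across layers: mus'(lambda) = a (lambda/500)^-b
  musp <- outer(samples$mus500, (grid / 500), function(a, x) a) *
    exp(outer(-samples$scatter_power, log(grid / 500)))
  r_total <- NULL
  for (layer in 3:1) {
    bvf <- samples[[paste0("bvf_", layer)]]
    sox <- samples[[paste0("sox_", layer)]]
    d_cm <- samples[[paste0("thickness_um_", layer)]] * 1e-4
    mua <- outer(bvf * sox, oxy) + outer(bvf * (1 - sox), deoxy) +
      samples$mua_background
    albedo <- musp / (mua + musp)
    r_layer <- r_infinity(albedo)
    if (layer == 3) {
      r_total <- r_layer  # bottom layer semi-infinite
    } else {
      tr <- exp(-2 * (mua + musp) * d_cm)
      r_total <- (1 - tr) * r_layer + tr * r_total
    }
  }
  pmin(pmax(r_total, 0), 1)
}

#' Camera model
#'
#' Band response curves and sensor characteristics of the simulated snapshot
#' multispectral camera: `n_bands` Gaussian responses with the given centers
#' and full width at half maximum, a 10-bit ADC by default, and a linear
#' dark-current model `dark_offset + dark_rate * exposure_ms` with Gaussian
#' read noise.
#'
#' @param grid A [wavelength_grid()].
#' @param n_bands Number of bands (default 16).
#' @param centers Band centers in nm (default evenly spaced 465-630 nm).
#' @param fwhm Full width at half maximum of each response, nm (default 15).
#' @param adc_bits ADC resolution (default 10, so `adc_max = 1023`).
#' @param dark_offset Dark counts at zero exposure (default 20).
#' @param dark_rate Dark counts per ms of exposure (default 1; snapshot
#'   mosaic sensors accumulate appreciable dark signal, which is what makes
#'   the goodness metric's normalization by the dark level informative).
#' @param read_noise_sd Read noise standard deviation in counts (default 2).
#' @param reference_exposure_ms Exposure at which analog scene signal is
#'   specified (default 40 ms).
#' @return A `camera_model` object; `$response` is the `n_bands x n_lambda`
#'   matrix of curves.
#' @export
camera_model <- function(grid = wavelength_grid(), n_bands = 16,
                         centers = seq(465, 630, length.out = n_bands),
                         fwhm = 15, adc_bits = 10, dark_offset = 20,
                         dark_rate = 1, read_noise_sd = 2,
                         reference_exposure_ms = 40) {
  if (length(centers) != n_bands) stop_config("One center per band required.")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  resp <- t(vapply(centers, function(cc) exp(-((grid - cc)^2) / (2 * sigma^2)),
                   numeric(length(grid))))
  if (any(rowSums(resp) <= 0)) stop_config("Every band response needs positive mass.")
  structure(
    list(
      grid = grid, response = resp, centers = centers, fwhm = fwhm,
      n_bands = n_bands, adc_bits = adc_bits, adc_max = 2^adc_bits - 1,
      dark_offset = dark_offset, dark_rate = dark_rate,
      read_noise_sd = read_noise_sd,
      reference_exposure_ms = reference_exposure_ms,
      band_ids = sprintf("b%02d", seq_len(n_bands))
    ),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "<camera_model> %d bands %g-%g nm (FWHM %g nm), %d-bit ADC, dark %g + %g/ms\n",
    x$n_bands, min(x$centers), max(x$centers), x$fwhm, x$adc_bits,
    x$dark_offset, x$dark_rate
  ))
  invisible(x)
}

#' Integrate reflectance spectra into camera bands
#'
#' `I_k = alpha * w_k * integral( xi_k(lambda) L(lambda) r(lambda) dlambda )`
#' by the trapezoidal rule on the camera grid; `w_k` is i.i.d. multiplicative
#' band noise `Normal(1, sigma_w)` truncated at 0 (deterministic when
#' `sigma_w = 0`).
#'
#' @param r Reflectance: vector on the grid or `n x n_lambda` matrix.
#' @param illuminant Illuminant spectral irradiance on the same grid.
#' @param camera A [camera_model()].
#' @param alpha Multiplicative gain, recycled over rows.
#' @param sigma_w Multiplicative noise standard deviation (default 0).
#' @param seed Optional RNG seed.
#' @return `n x n_bands` matrix of band measurements (no quantization).
#' @export
band_integrate <- function(r, illuminant, camera, alpha = 1, sigma_w = 0,
                           seed = NULL) {
  if (is.null(dim(r))) r <- matrix(r, nrow = 1)
  nl <- length(camera$grid)
  if (ncol(r) != nl || length(illuminant) != nl) {
    stop_dimension("Reflectance/illuminant must live on the camera's grid.")
  }
  w <- trapezoid_weights(camera$grid)
  proj <- t(camera$response * rep(illuminant * w, each = camera$n_bands))
  bands <- (r %*% proj) * alpha
  if (sigma_w > 0) {
    noise <- with_seed(seed,
      matrix(pmax(rnorm(length(bands), 1, sigma_w), 0), nrow = nrow(bands)))
    bands <- bands * noise
  }
  colnames(bands) <- camera$band_ids
  bands
}
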