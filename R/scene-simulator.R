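#' Dichromatic surgical-scene description
#'
#' Builds the per-pixel fields of a synthetic dichromatic scene: a tissue
#' assignment (nearest-center regions over a few sampled tissue types), a
#' specular strength field `c(i,j)` made of Gaussian-profile highlight blobs
#' (zero outside their support), and a per-pixel gain field `alpha(i,j)`.
#' Per the dichromatic reflection model the analog signal of a pixel is
#' `alpha * diffuse_bands(tissue) + c * illuminant_bands`, where the specular
#' term uses flat unit reflectance (neutral-interface assumption).
#'
#' Intensity scale: the tissue diffuse term is scaled so its grand mean is
#' `diffuse_level` ADC counts at the camera's reference exposure, and `c` is
#' expressed in multiples of that level, so `highlight_contrast` is directly
#' the peak specular-to-diffuse contrast.
#'
#' @param illuminant True illuminant on the camera's wavelength grid.
#' @param camera A [camera_model()].
#' @param width,height Scene size in pixels (default 128 x 128).
#' @param tissue_samples Optional [sample_tissue()] tibble; default samples
#'   `n_tissue_regions` fresh ones.
#' @param n_tissue_regions Number of tissue regions (default 3).
#' @param n_highlights Number of highlight blobs (default 12).
#' @param highlight_sigma_px Range of blob radii, px (default 2-5).
#' @param highlight_contrast Range of peak specular-to-diffuse contrast,
#'   drawn log-uniformly (default 8-45). Blobs model true glare — mirror-like
#'   reflection of the source off wet tissue, which exceeds the body
#'   reflection many-fold by nature; the faint end of the specular continuum
#'   is carried by the sheen population instead.
#' @param highlight_profile_order Super-Gaussian order of the blob profile
#'   (default 2): glare spots have a bright plateau falling off sharply at
#'   the rim, so once the core saturates few near-ceiling rim pixels remain
#'   and the goodness metric drops — the behaviour that makes exposure
#'   selection meaningful. Order 1 recovers a plain Gaussian profile.
#' @param n_sheen Number of broad faint gloss patches (default 3): wet-tissue
#'   sheen gives large areas of weak specular reflection that remain valid at
#'   long exposures, where the strong blobs have long saturated.
#' @param sheen_sigma_px Range of sheen patch radii, px (default 8-16).
#' @param sheen_contrast Range of peak sheen-to-diffuse contrast, drawn
#'   log-uniformly (default 1.5-4).
#' @param gain_range Range of the per-pixel multiplicative gain (default
#'   0.7-1.3).
#' @param sigma_w Multiplicative band-noise standard deviation (default 0.1).
#' @param diffuse_level Mean diffuse signal in counts at reference exposure
#'   (default 100; dark organs such as liver reflect weakly compared with
#'   specular glare).
#' @param diffuse_in_highlights If `FALSE`, the diffuse term is zeroed under
#'   highlight blobs (glare fully occludes body reflection) — used for
#'   noise-free purity checks.
#' @param table A [chromophore_table()] on the camera grid.
#' @param seed Optional RNG seed for the geometry and tissue draw.
#' @return A `dichromatic_scene` object.
#' @export
dichromatic_scene <- function(illuminant, camera, width = 128, height = 128,
                              tissue_samples = NULL, n_tissue_regions = 3,
                              n_highlights = 12, highlight_sigma_px = c(2, 5),
                              highlight_contrast = c(8, 45),
                              highlight_profile_order = 2,
                              n_sheen = 3, sheen_sigma_px = c(8, 16),
                              sheen_contrast = c(1.5, 4),
                              gain_range = c(0.7, 1.3), sigma_w = 0.1,
                              diffuse_level = 100, diffuse_in_highlights = TRUE,
                              table = chromophore_table(camera$grid),
                              seed = NULL) {
  if (length(illuminant) != length(camera$grid)) {
    stop_dimension("Illuminant must live on the camera's grid.")
  }
  with_seed(seed, {
    if (is.null(tissue_samples)) tissue_samples <- sample_tissue(n_tissue_regions)
    n_tissue <- nrow(tissue_samples)
    # nearest-center tissue regions
    cx <- runif(n_tissue, 1, height); cy <- runif(n_tissue, 1, width)
    px_row <- rep(seq_len(height), times = width)
    px_col <- rep(seq_len(width), each = height)
    d2 <- vapply(seq_len(n_tissue),
                 function(t) (px_row - cx[t])^2 + (px_col - cy[t])^2,
                 numeric(height * width))
    tissue_idx <- matrix(max.col(-d2), nrow = height, ncol = width)
    # specular strength field: sum of compact Gaussian blobs
    cfield <- matrix(0, height, width)
    for (b in seq_len(n_highlights)) {
      bx <- runif(1, 5, height - 4); by <- runif(1, 5, width - 4)
      sig <- runif(1, highlight_sigma_px[1], highlight_sigma_px[2])
      peak <- exp(runif(1, log(highlight_contrast[1]), log(highlight_contrast[2])))
      d2b <- ((px_row - bx)^2 + (px_col - by)^2) / (2 * sig^2)
      blob <- peak * exp(-d2b^highlight_profile_order)
      blob[blob < 0.01] <- 0
      cfield <- cfield + matrix(blob, height, width)
    }
    for (b in seq_len(n_sheen)) {
      bx <- runif(1, 5, height - 4); by <- runif(1, 5, width - 4)
      sig <- runif(1, sheen_sigma_px[1], sheen_sigma_px[2])
      peak <- exp(runif(1, log(sheen_contrast[1]), log(sheen_contrast[2])))
      d2b <- ((px_row - bx)^2 + (px_col - by)^2) / (2 * sig^2)
      blob <- peak * exp(-d2b^highlight_profile_order)
      blob[blob < 0.01] <- 0
      cfield <- cfield + matrix(blob, height, width)
    }
    alpha <- matrix(runif(height * width, gain_range[1], gain_range[2]),
                    height, width)
    if (!diffuse_in_highlights) alpha[cfield > 0] <- 0
    # diffuse band signature per tissue type, scaled to diffuse_level counts
    refl <- reflectance_spectrum(tissue_samples, camera$grid, table)
    diffuse_bands <- band_integrate(refl, illuminant, camera)
    scale <- diffuse_level / mean(diffuse_bands)
    diffuse_bands <- diffuse_bands * scale
    illum_bands <- as.numeric(band_integrate(rep(1, length(camera$grid)),
                                             illuminant, camera))
    illum_bands <- illum_bands / mean(illum_bands) * diffuse_level
    structure(
      list(
        width = width, height = height,
        tissue_samples = tissue_samples, tissue_idx = tissue_idx,
        cfield = cfield, alpha = alpha,
        diffuse_bands = diffuse_bands, illum_bands = illum_bands,
        illuminant = illuminant, camera = camera, sigma_w = sigma_w
      ),
      class = "dichromatic_scene"
    )
  })
}

#' @export
print.dichromatic_scene <- function(x, ...) {
  cat(sprintf(
    "<dichromatic_scene> %d x %d px, %d tissue regions, %d highlight px, sigma_w = %g\n",
    x$height, x$width, nrow(x$tissue_samples), sum(x$cfield > 0), x$sigma_w
  ))
  invisible(x)
}

#' Render a scene at one exposure
#'
#' The analog band signal (diffuse + specular, scaled linearly by
#' `exposure / reference_exposure`) receives multiplicative band noise,
#' dark counts (`dark_offset + dark_rate * exposure`) and Gaussian read
#' noise, then is quantized to integers and clipped to `[0, adc_max]`.
#'
#' @param scene A [dichromatic_scene()].
#' @param exposure_ms Exposure time (> 0).
#' @param seed Optional RNG seed for the noise draws.
#' @return List with `cube` (a [spectral_cube()]) and `truth`: the true
#'   illuminant on the grid, its band-space rendering (L1-normalized), the
#'   per-pixel first-layer oxygenation map, and the specular-dominant pixel
#'   mask (specular band-sum > 10 x diffuse band-sum).
#' @export
generate_scene <- function(scene, exposure_ms, seed = NULL) {
  stopifnot(inherits(scene, "dichromatic_scene"))
  if (!is.numeric(exposure_ms) || exposure_ms <= 0) {
    stop_config("`exposure_ms` must be > 0.")
  }
  cam <- scene$camera
  npix <- scene$height * scene$width
  nb <- cam$n_bands
  diffuse <- scene$diffuse_bands[as.vector(scene$tissue_idx), , drop = FALSE] *
    as.vector(scene$alpha)
  specular <- outer(as.vector(scene$cfield), scene$illum_bands)
  analog <- (diffuse + specular) * (exposure_ms / cam$reference_exposure_ms)
  with_seed(seed, {
    if (scene$sigma_w > 0) {
      analog <- analog * matrix(pmax(rnorm(npix * nb, 1, scene$sigma_w), 0),
                                npix, nb)
    }
    counts <- analog + cam$dark_offset + cam$dark_rate * exposure_ms
    if (cam$read_noise_sd > 0) {
      counts <- counts + rnorm(npix * nb, 0, cam$read_noise_sd)
    }
    counts <- pmin(pmax(round(counts), 0), cam$adc_max)
    cube <- spectral_cube(array(counts, dim = c(scene$height, scene$width, nb)),
                          exposure_ms = exposure_ms, band_ids = cam$band_ids)
    truth <- list(
      illuminant = scene$illuminant,
      illuminant_bands = illuminant_spectrum(scene$illum_bands,
                                             band_ids = cam$band_ids),
      sox_map = matrix(scene$tissue_samples$sox_1[as.vector(scene$tissue_idx)],
                       scene$height, scene$width),
      specular_dominant = matrix(rowSums(specular) > 10 * rowSums(diffuse),
                                 scene$height, scene$width)
    )
    list(cube = cube, truth = truth)
  })
}

#' Render a dark frame
#'
#' A cube with zero scene signal: dark counts plus read noise, quantized and
#' clipped. Its mean lightness defines the dark level `Dbar(T_exp)`.
#'
#' @param camera A [camera_model()].
#' @param exposure_ms Exposure time (> 0).
#' @param shape `c(rows, cols)` of the frame (default 64 x 64).
#' @param seed Optional RNG seed.
#' @return A [spectral_cube()].
#' @export
generate_dark_frame <- function(camera, exposure_ms, shape = c(64, 64),
                                seed = NULL) {
  if (!is.numeric(exposure_ms) || exposure_ms <= 0) {
    stop_config("`exposure_ms` must be > 0.")
  }
  n <- prod(shape) * camera$n_bands
  with_seed(seed, {
    counts <- camera$dark_offset + camera$dark_rate * exposure_ms
    if (camera$read_noise_sd > 0) counts <- counts + rnorm(n, 0, camera$read_noise_sd)
    counts <- pmin(pmax(round(counts), 0), camera$adc_max)
    spectral_cube(array(counts, dim = c(shape, camera$n_bands)),
                  exposure_ms = exposure_ms, band_ids = camera$band_ids)
  })
}

#' Dark-current statistics over an exposure sweep
#'
#' Renders one dark frame per exposure and summarizes its lightness image —
#' mirroring the physical calibration procedure (lights off) rather than
#' using the closed-form dark model.
#'
#' @param camera A [camera_model()].
#' @param exposures Exposure times in ms.
#' @param shape Dark-frame size (default 64 x 64).
#' @param seed Optional RNG seed.
#' @return Tibble with columns `exposure_ms`, `dark_mean`, `dark_std`.
#' @export
dark_statistics <- function(camera, exposures, shape = c(64, 64), seed = NULL) {
  seeds <- derive_seeds(seed, length(exposures))
  purrr::map_dfr(seq_along(exposures), function(i) {
    lf <- lightness(generate_dark_frame(camera, exposures[i], shape, seeds[[i]]))
    tibble::tibble(exposure_ms = exposures[i],
                   dark_mean = mean(lf), dark_std = sd(as.vector(lf)))
  })
}

#' Render an exposure series of a scene
#'
#' One cube per exposure (default the 5-150 ms sweep in 5 ms steps) plus
#' per-exposure dark statistics from rendered dark frames.
#'
#' @param scene A [dichromatic_scene()].
#' @param exposures Strictly increasing exposure times, ms.
#' @param seed Optional RNG seed.
#' @param dark_stats Optional precomputed [dark_statistics()] table (the
#'   camera's dark behaviour is scene-independent, so it can be shared).
#' @return An [exposure_series()].
#' @export
generate_exposure_series <- function(scene, exposures = seq(5, 150, by = 5),
                                     seed = NULL, dark_stats = NULL) {
  if (length(exposures) == 0) stop_config("Exposure list must be non-empty.")
  if (any(diff(exposures) <= 0)) stop_config("Exposures must be strictly increasing.")
  seeds <- derive_seeds(seed, length(exposures) + 1)
  cubes <- purrr::map(seq_along(exposures), function(i) {
    generate_scene(scene, exposures[i], seed = seeds[[i]])$cube
  })
  if (is.null(dark_stats)) {
    dark_stats <- dark_statistics(scene$camera, exposures,
                                  seed = seeds[[length(exposures) + 1]])
  }
  exposure_series(cubes, dark_stats)
}
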