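#' Validity thresholds for highlight segmentation
#'
#' A pixel is *valid* when every band intensity lies strictly inside
#' `(i_min, i_max)`. `i_min` is the dark-current level for the exposure at
#' hand; `i_max` guards against the sensor's nonlinear/saturating range
#' (default 950 counts on a 10-bit sensor).
#'
#' @param i_min Lower threshold in ADC counts (`0 <= i_min < i_max`).
#' @param i_max Upper threshold in ADC counts.
#' @return A `validity_thresholds` object.
#' @export
validity_thresholds <- function(i_min, i_max = 950) {
  if (!is.numeric(i_min) || !is.numeric(i_max) || length(i_min) != 1 ||
      length(i_max) != 1 || is.na(i_min) || is.na(i_max)) {
    stop_config("Thresholds must be single numbers.")
  }
  if (i_min < 0 || i_min >= i_max) stop_config("Need 0 <= i_min < i_max.")
  structure(list(i_min = i_min, i_max = i_max), class = "validity_thresholds")
}

# i_min policy: dark mean lightness + 3 sd, for the exposure at hand.
i_min_from_dark <- function(dark_mean, dark_std) dark_mean + 3 * dark_std

#' Valid-pixel mask of a cube
#'
#' @param cube A [spectral_cube()].
#' @param thresholds A [validity_thresholds()].
#' @return Logical `rows x cols` matrix; `TRUE` where all bands lie strictly
#'   inside `(i_min, i_max)`. An all-`FALSE` mask is legal output.
#' @export
compute_valid_mask <- function(cube, thresholds) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(thresholds, "validity_thresholds"))
  d <- dim(cube$data)
  m <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  ok <- rowSums(m > thresholds$i_min & m < thresholds$i_max) == d[3]
  matrix(ok, nrow = d[1], ncol = d[2])
}

#' Select specular-highlight pixels
#'
#' Picks the `n_p` valid pixels of greatest lightness (all valid pixels when
#' fewer exist). Ties are broken deterministically: descending lightness, then
#' ascending row, then ascending column.
#'
#' @param lightness_image Numeric matrix, e.g. from [lightness()].
#' @param mask Logical matrix of the same shape (valid pixels).
#' @param n_p Number of highlight pixels requested (default 100).
#' @return A tibble of class `highlight_selection` with columns `row`, `col`
#'   (1-based) and `lightness`, ordered by the tie-break rule.
#' @export
select_highlight_pixels <- function(lightness_image, mask, n_p = 100) {
  if (!all(dim(lightness_image) == dim(mask))) {
    stop_dimension("Lightness image and mask shapes differ.")
  }
  if (!is.numeric(n_p) || length(n_p) != 1 || n_p < 1) {
    stop_config("`n_p` must be a positive count.")
  }
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop_no_highlights("No valid pixels; try another exposure.")
  lv <- lightness_image[idx]
  ord <- order(-lv, idx[, 1], idx[, 2])
  take <- ord[seq_len(min(n_p, length(ord)))]
  out <- tibble::tibble(
    row = as.integer(idx[take, 1]),
    col = as.integer(idx[take, 2]),
    lightness = lv[take]
  )
  class(out) <- c("highlight_selection", class(out))
  attr(out, "n_p") <- as.integer(n_p)
  out
}

#' Estimate the illuminant from highlight pixels
#'
#' Each selected pixel's band vector is L1-normalized, so every highlight
#' pixel contributes one unit-mass illuminant estimate; the final estimate is
#' the mean of these, re-normalized to sum exactly 1. An optional scalar dark
#' level is subtracted from every band first (clamped at 0) — standard
#' dark-frame correction for low-exposure images.
#'
#' @param cube A [spectral_cube()].
#' @param selection A [select_highlight_pixels()] result (non-empty).
#' @param dark_level Scalar dark-current level in counts to subtract
#'   per band (default 0, i.e. no correction).
#' @return Named numeric vector (band ids) of class `illuminant_spectrum`,
#'   summing to 1.
#' @export
estimate_illuminant <- function(cube, selection, dark_level = 0) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (NROW(selection) == 0) stop_degenerate("Empty highlight selection.")
  d <- dim(cube$data)
  flat <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  pix <- flat[selection$row + (selection$col - 1L) * d[1], , drop = FALSE]
  pix <- pmax(pix - dark_level, 0)
  sums <- rowSums(pix)
  if (any(sums <= 0)) stop_degenerate("A selected pixel has zero total intensity.")
  est <- colMeans(pix / sums)
  illuminant_spectrum(est / sum(est), band_ids = cube$band_ids)
}

#' Illuminant spectrum container
#'
#' @param values Non-negative per-band relative irradiance.
#' @param band_ids Optional labels.
#' @param normalize L1-normalize on construction (default TRUE).
#' @return Numeric vector of class `illuminant_spectrum`.
#' @export
illuminant_spectrum <- function(values, band_ids = NULL, normalize = TRUE) {
  if (anyNA(values) || any(values < 0) || sum(values) <= 0) {
    stop_degenerate("Illuminant values must be >= 0 with positive sum.")
  }
  nm <- if (!is.null(band_ids)) as.character(band_ids) else names(values)
  v <- as.numeric(if (normalize) values / sum(values) else values)
  if (!is.null(nm)) {
    if (length(nm) != length(v)) stop_dimension("One band id per value required.")
    names(v) <- nm
  }
  structure(v, class = "illuminant_spectrum")
}

#' @export
print.illuminant_spectrum <- function(x, ...) {
  cat(sprintf("<illuminant_spectrum> %d bands, sum = %g\n", length(x), sum(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Exposure series container
#'
#' Bracketed cubes of the same scene at increasing exposure times, together
#' with per-exposure dark-current statistics (mean and sd of dark-frame
#' lightness).
#'
#' @param cubes List of [spectral_cube()]s, each with `exposure_ms` set,
#'   strictly increasing.
#' @param dark_stats Data frame with columns `exposure_ms`, `dark_mean`,
#'   `dark_std` covering every exposure in `cubes`.
#' @return An `exposure_series` object.
#' @export
exposure_series <- function(cubes, dark_stats) {
  if (length(cubes) == 0) stop_config("Exposure series must be non-empty.")
  exps <- vapply(cubes, function(cc) {
    if (!inherits(cc, "spectral_cube") || is.null(cc$exposure_ms)) {
      stop_config("Every series entry needs an exposure time.")
    }
    cc$exposure_ms
  }, numeric(1))
  if (any(diff(exps) <= 0)) stop_config("Exposure times must be strictly increasing.")
  dark_stats <- tibble::as_tibble(dark_stats)
  need <- c("exposure_ms", "dark_mean", "dark_std")
  if (!all(need %in% names(dark_stats))) {
    stop_format("dark_stats needs columns exposure_ms, dark_mean, dark_std.")
  }
  if (!all(exps %in% dark_stats$exposure_ms)) {
    stop_config("Dark statistics missing for some exposures.")
  }
  structure(list(cubes = cubes, exposures = exps, dark_stats = dark_stats),
            class = "exposure_series")
}

#' @export
print.exposure_series <- function(x, ...) {
  cat(sprintf("<exposure_series> %d exposures: %s ms\n",
              length(x$exposures), paste(x$exposures, collapse = ", ")))
  invisible(x)
}

dark_row <- function(series, exposure_ms) {
  i <- match(exposure_ms, series$dark_stats$exposure_ms)
  series$dark_stats[i, ]
}

#' Goodness metric of a calibration image
#'
#' `G` is the median, over the selected highlight pixels, of the relative
#' excess of lightness over the mean dark-current lightness:
#' `median((I_L - Dbar) / Dbar)`. Larger `G` indicates brighter, still-valid
#' highlights and empirically lower calibration error.
#'
#' @param selection A [select_highlight_pixels()] result.
#' @param dark_lightness_mean Mean dark lightness `Dbar` for the exposure (> 0).
#' @return The scalar goodness value.
#' @export
goodness <- function(selection, dark_lightness_mean) {
  if (NROW(selection) == 0) stop_degenerate("Empty highlight selection.")
  if (!is.numeric(dark_lightness_mean) || dark_lightness_mean <= 0) {
    stop_config("Dark statistics required: Dbar must be > 0.")
  }
  median((selection$lightness - dark_lightness_mean) / dark_lightness_mean)
}

series_profile <- function(series, i_max, n_p) {
  purrr::map_dfr(seq_along(series$cubes), function(i) {
    cube <- series$cubes[[i]]
    dk <- dark_row(series, cube$exposure_ms)
    thr <- validity_thresholds(i_min_from_dark(dk$dark_mean, dk$dark_std), i_max)
    mask <- compute_valid_mask(cube, thr)
    sel <- tryCatch(
      select_highlight_pixels(lightness(cube), mask, n_p),
      speclight_error_no_highlights = function(e) NULL
    )
    tibble::tibble(
      exposure_ms = cube$exposure_ms,
      n_valid = sum(mask),
      n_selected = NROW(sel),
      goodness = if (is.null(sel)) -Inf else goodness(sel, dk$dark_mean),
      selection = list(sel),
      i_min = thr$i_min,
      dark_mean = dk$dark_mean
    )
  })
}

#' Choose the calibration exposure by maximum goodness
#'
#' Computes the goodness profile `G(T_exp)` over the series (exposures with no
#' valid highlight pixel get `G = -Inf` and are never chosen) and returns the
#' exposure maximizing `G`; ties go to the shorter exposure.
#'
#' @param series An [exposure_series()].
#' @param i_max Upper validity threshold in counts (default 950).
#' @param n_p Highlight-pixel count (default 100).
#' @return List with `exposure_ms` (the winner) and `profile`, a tibble with
#'   one row per exposure (`exposure_ms`, `n_valid`, `n_selected`, `goodness`).
#' @export
select_exposure <- function(series, i_max = 950, n_p = 100) {
  stopifnot(inherits(series, "exposure_series"))
  prof <- series_profile(series, i_max, n_p)
  if (all(!is.finite(prof$goodness))) {
    stop_no_highlights("No exposure in the series yields valid highlight pixels.")
  }
  best <- which(prof$goodness == max(prof$goodness))[1]  # rows sorted by exposure
  list(
    exposure_ms = prof$exposure_ms[best],
    profile = dplyr::select(prof, "exposure_ms", "n_valid", "n_selected", "goodness")
  )
}

#' Calibrate the light source from a low-exposure series
#'
#' End-to-end specular-highlight calibration: per exposure, the lower validity
#' threshold is set from the dark statistics (`mean + 3 sd`), valid pixels are
#' masked, the `n_p` brightest valid pixels are selected and the goodness
#' metric computed; the exposure with maximum goodness wins and its
#' dark-corrected, L1-normalized highlight spectra are averaged into the
#' illuminant estimate.
#'
#' @param series An [exposure_series()].
#' @param i_max Upper validity threshold (counts, default 950).
#' @param n_p Highlight pixels per image (default 100).
#' @return An object of class `light_calibration`: list with `estimate`
#'   (an `illuminant_spectrum`), `exposure_ms`, `goodness`, `selection`,
#'   `profile`, and `mask` for the winning exposure.
#' @export
calibrate <- function(series, i_max = 950, n_p = 100) {
  stopifnot(inherits(series, "exposure_series"))
  prof <- series_profile(series, i_max, n_p)
  if (all(!is.finite(prof$goodness))) {
    stop_no_highlights("No exposure in the series yields valid highlight pixels.")
  }
  best <- which(prof$goodness == max(prof$goodness))[1]
  cube <- series$cubes[[best]]
  sel <- prof$selection[[best]]
  dk <- dark_row(series, cube$exposure_ms)
  thr <- validity_thresholds(prof$i_min[best], i_max)
  est <- estimate_illuminant(cube, sel, dark_level = dk$dark_mean)
  structure(
    list(
      estimate = est,
      exposure_ms = cube$exposure_ms,
      goodness = prof$goodness[best],
      selection = sel,
      profile = dplyr::select(prof, "exposure_ms", "n_valid", "n_selected", "goodness"),
      mask = compute_valid_mask(cube, thr)
    ),
    class = "light_calibration"
  )
}

#' @export
print.light_calibration <- function(x, ...) {
  cat(sprintf(
    "<light_calibration> exposure %g ms, G = %.3g, %d highlight pixels, %d bands\n",
    x$exposure_ms, x$goodness, NROW(x$selection), length(x$estimate)
  ))
  invisible(x)
}
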