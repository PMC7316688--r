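#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an illuminant spectrum
#'
#' @param x An `illuminant_spectrum`.
#' @param ... Unused.
#' @return Tibble with columns `band`, `value`.
#' @method tidy illuminant_spectrum
#' @export
tidy.illuminant_spectrum <- function(x, ...) {
  tibble::tibble(
    band = if (is.null(names(x))) sprintf("b%02d", seq_along(x)) else names(x),
    value = as.numeric(x)
  )
}

#' Tidy a calibration result
#'
#' @param x A [calibrate()] result.
#' @param ... Unused.
#' @return Per-band estimate as a tibble (`band`, `value`).
#' @method tidy light_calibration
#' @export
tidy.light_calibration <- function(x, ...) tidy(x$estimate)

#' One-row summary of a calibration result
#'
#' @param x A [calibrate()] result.
#' @param ... Unused.
#' @return Tibble with `exposure_ms`, `goodness`, `n_highlight_pixels`,
#'   `n_valid_pixels`, `n_exposures`.
#' @method glance light_calibration
#' @export
glance.light_calibration <- function(x, ...) {
  tibble::tibble(
    exposure_ms = x$exposure_ms,
    goodness = x$goodness,
    n_highlight_pixels = NROW(x$selection),
    n_valid_pixels = sum(x$mask),
    n_exposures = nrow(x$profile)
  )
}

#' Tidy the mismatch experiment
#'
#' @param x A [run_illuminant_mismatch_experiment()] result.
#' @param ... Unused.
#' @return The per-condition results tibble.
#' @method tidy mismatch_experiment
#' @export
tidy.mismatch_experiment <- function(x, ...) x$results

#' One-row summary of the mismatch experiment
#'
#' @param x A [run_illuminant_mismatch_experiment()] result.
#' @param ... Unused.
#' @return Tibble with mean MAE per condition and the mean relative error
#'   reduction of calibration (percent), when the calibrated condition ran.
#' @method glance mismatch_experiment
#' @export
glance.mismatch_experiment <- function(x, ...) {
  m <- function(cond) {
    v <- x$results$mae_pp[x$results$condition == cond]
    if (length(v)) mean(v) else NA_real_
  }
  tibble::tibble(
    mean_mae_matched_pp = m("matched"),
    mean_mae_mismatched_pp = m("mismatched"),
    mean_mae_calibrated_pp = m("calibrated"),
    mean_reduction_pct = if ("reduction_pct" %in% names(x$summary)) {
      mean(x$summary$reduction_pct)
    } else NA_real_
  )
}

#' Plot an illuminant spectrum
#'
#' @param object An `illuminant_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot illuminant_spectrum
#' @export
autoplot.illuminant_spectrum <- function(object, ...) {
  d <- tidy(object)
  d$band_index <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$band_index, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "band", y = "relative irradiance (L1-normalized)")
}

#' Plot a calibration result: goodness profile and chosen exposure
#'
#' @param object A [calibrate()] result.
#' @param ... Unused.
#' @return A ggplot of `G` against exposure time with the winner marked.
#' @method autoplot light_calibration
#' @export
autoplot.light_calibration <- function(object, ...) {
  prof <- object$profile
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$exposure_ms, y = .data$goodness)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$exposure_ms, linetype = 2) +
    ggplot2::labs(x = "exposure (ms)", y = "goodness G")
}

#' Plot the mismatch experiment
#'
#' @param object A [run_illuminant_mismatch_experiment()] result.
#' @param ... Unused.
#' @return A ggplot: oxygenation MAE per condition and test illuminant.
#' @method autoplot mismatch_experiment
#' @export
autoplot.mismatch_experiment <- function(object, ...) {
  ggplot2::ggplot(
    object$results,
    ggplot2::aes(x = .data$condition, y = .data$mae_pp, fill = .data$condition)
  ) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~test_ls) +
    ggplot2::labs(x = NULL, y = "oxygenation MAE (pp)")
}

#' Plot a calibration study
#'
#' @param object A [simulate_calibration_study()] tibble.
#' @param ... Unused.
#' @return A ggplot of angular error per illuminant.
#' @method autoplot calibration_study
#' @export
autoplot.calibration_study <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$illuminant_id, y = .data$angular_error_deg)
  ) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "light source", y = "angular error (deg)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
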