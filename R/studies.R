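#' Run the synthetic calibration validation study
#'
#' For each illuminant, renders `n_scenes` independent dichromatic scenes
#' (fresh highlight geometry, gain field and tissue draw per scene — the
#' analog of varying camera pose), generates the low-exposure series, runs
#' the full specular-highlight calibration and records the angular error to
#' the true illuminant in band space.
#'
#' @param illuminants Named list of true illuminants on the camera grid
#'   (default [reference_illuminants()]).
#' @param camera A [camera_model()].
#' @param n_scenes Scenes (pose analogs) per illuminant (default 8).
#' @param exposures Exposure sweep, ms (default 5-150 by 5).
#' @param noise_free If `TRUE`, disables band noise and read noise and uses
#'   specular-only highlight blobs — the idealized configuration in which
#'   recovery should be essentially exact.
#' @param scene_args Extra arguments passed to [dichromatic_scene()].
#' @param seed RNG seed.
#' @return Tibble of class `calibration_study`: one row per run with
#'   `illuminant_id`, `scene`, `exposure_ms`, `goodness`,
#'   `angular_error_deg`, and list-columns `estimate` (band space) and
#'   `truth_bands`.
#' @export
simulate_calibration_study <- function(illuminants = NULL, camera = camera_model(),
                                       n_scenes = 8,
                                       exposures = seq(5, 150, by = 5),
                                       noise_free = FALSE, scene_args = list(),
                                       seed = NULL) {
  if (is.null(illuminants)) illuminants <- reference_illuminants(camera$grid)
  if (noise_free) {
    camera$read_noise_sd <- 0
    scene_args$sigma_w <- 0
    scene_args$diffuse_in_highlights <- FALSE
  }
  seeds <- derive_seeds(seed, length(illuminants) * n_scenes + 1)
  dark <- dark_statistics(camera, exposures, seed = seeds[[length(seeds)]])
  table <- chromophore_table(camera$grid)
  k <- 0
  out <- purrr::map_dfr(names(illuminants), function(id) {
    purrr::map_dfr(seq_len(n_scenes), function(s) {
      k <<- k + 1
      run_seeds <- derive_seeds(seeds[[k]], 2)
      scene <- do.call(dichromatic_scene, c(
        list(illuminant = illuminants[[id]], camera = camera, table = table,
             seed = run_seeds[[1]]),
        scene_args
      ))
      series <- generate_exposure_series(scene, exposures, seed = run_seeds[[2]],
                                         dark_stats = dark)
      cal <- calibrate(series)
      truth <- as.numeric(band_integrate(rep(1, length(camera$grid)),
                                         illuminants[[id]], camera))
      tibble::tibble(
        illuminant_id = id, scene = s,
        exposure_ms = cal$exposure_ms, goodness = cal$goodness,
        angular_error_deg = angular_error(cal$estimate, truth),
        estimate = list(cal$estimate),
        truth_bands = list(illuminant_spectrum(truth, band_ids = camera$band_ids))
      )
    })
  })
  class(out) <- c("calibration_study", class(out))
  attr(out, "camera") <- camera
  out
}

#' Compare baselines against the specular-highlight method
#'
#' Renders each study scene at fixed exposure analogs and applies the four
#' model-based estimators to the full image and the specular-highlight
#' estimator to the same cube (valid-mask segmentation, top-`n_p` selection,
#' dark-corrected averaging), recording angular errors per method.
#'
#' @param illuminants Named list of true illuminants on the camera grid.
#' @param camera A [camera_model()].
#' @param n_scenes Scenes per illuminant (default 8).
#' @param exposures Fixed exposure analogs in ms (default low/normal/high =
#'   20/40/60).
#' @param p,sigma Baseline hyperparameters (Minkowski order 6, smoothing 2 px).
#' @param n_p Highlight pixels for the specular method (default 100).
#' @param scene_args Extra arguments for [dichromatic_scene()].
#' @param seed RNG seed.
#' @return Tibble with `illuminant_id`, `scene`, `exposure_ms`, `method`,
#'   `angular_error_deg`.
#' @export
compare_baselines <- function(illuminants = NULL, camera = camera_model(),
                              n_scenes = 8, exposures = c(20, 40, 60),
                              p = 6, sigma = 2, n_p = 100,
                              scene_args = list(), seed = NULL) {
  if (is.null(illuminants)) illuminants <- reference_illuminants(camera$grid)
  seeds <- derive_seeds(seed, length(illuminants) * n_scenes + 1)
  dark <- dark_statistics(camera, exposures, seed = seeds[[length(seeds)]])
  table <- chromophore_table(camera$grid)
  k <- 0
  purrr::map_dfr(names(illuminants), function(id) {
    truth <- as.numeric(band_integrate(rep(1, length(camera$grid)),
                                       illuminants[[id]], camera))
    purrr::map_dfr(seq_len(n_scenes), function(s) {
      k <<- k + 1
      run_seeds <- derive_seeds(seeds[[k]], 1 + length(exposures))
      scene <- do.call(dichromatic_scene, c(
        list(illuminant = illuminants[[id]], camera = camera, table = table,
             seed = run_seeds[[1]]),
        scene_args
      ))
      purrr::map_dfr(seq_along(exposures), function(e) {
        cube <- generate_scene(scene, exposures[e], seed = run_seeds[[e + 1]])$cube
        dk <- dark[dark$exposure_ms == exposures[e], ]
        thr <- validity_thresholds(i_min_from_dark(dk$dark_mean, dk$dark_std))
        mask <- compute_valid_mask(cube, thr)
        spec_est <- tryCatch({
          sel <- select_highlight_pixels(lightness(cube), mask, n_p)
          estimate_illuminant(cube, sel, dark_level = dk$dark_mean)
        }, speclight_error = function(e) NULL)
        ests <- list(
          max_rgb = max_rgb(cube),
          gray_world = gray_world(cube),
          shades_of_gray = shades_of_gray(cube, p = p),
          gray_edge = gray_edge(cube, p = p, sigma = sigma),
          specular_highlights = spec_est
        )
        purrr::map_dfr(names(ests), function(mth) {
          tibble::tibble(
            illuminant_id = id, scene = s, exposure_ms = exposures[e],
            method = mth,
            angular_error_deg = if (is.null(ests[[mth]])) NA_real_ else
              angular_error(ests[[mth]], truth)
          )
        })
      })
    })
  })
}

#' Experiment design for the illuminant-mismatch study
#'
#' @param illuminants Named list of true illuminants on the camera grid.
#' @param camera A [camera_model()].
#' @param estimates Optional tibble with columns `illuminant_id` (the true
#'   illuminant each estimate belongs to) and list-column `estimate`
#'   (band-space estimates, e.g. from [simulate_calibration_study()]);
#'   enables the calibrated condition.
#' @param n_train,n_test Training/test sizes per illuminant. Defaults are the
#'   desk-scale 2000/500; the full-scale study uses 10000/5000.
#' @param sigma_w Band-noise sd used when rendering measurements.
#' @param num_trees Forest size per regressor.
#' @param seed RNG seed.
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(illuminants = NULL, camera = camera_model(),
                              estimates = NULL, n_train = 2000, n_test = 500,
                              sigma_w = 0.1, num_trees = 200, seed = NULL) {
  if (is.null(illuminants)) illuminants <- reference_illuminants(camera$grid)
  if (length(illuminants) < 1) stop_config("Need at least one illuminant.")
  structure(
    list(illuminants = illuminants, camera = camera, estimates = estimates,
         n_train = n_train, n_test = n_test, n_total = n_train + n_test,
         sigma_w = sigma_w, num_trees = num_trees, seed = seed),
    class = "experiment_design"
  )
}

#' Run the illuminant-mismatch oxygenation experiment
#'
#' One pool of tissue samples is split into train/test; per illuminant a
#' training and a test set are rendered (identical ground-truth tissue
#' parameters across illuminants). A regressor is trained per true illuminant
#' and — when calibration estimates are supplied — per estimate. Oxygenation
#' MAE is evaluated per condition: *matched* (train and test under the same
#' illuminant), *mismatched* (every ordered pair of distinct illuminants) and
#' *calibrated* (regressor trained under the calibration estimate, tested
#' under the estimate's true illuminant). The summary reports the relative
#' error reduction `(1 - MAE_calibrated / MAE_mismatched) * 100` per test
#' illuminant and its mean.
#'
#' @param design An [experiment_design()].
#' @return A `mismatch_experiment` object with `$results` (tibble: `test_ls`,
#'   `condition`, `train_ls`, `mae_pp`), `$summary` (per test illuminant) and
#'   `$design`.
#' @export
run_illuminant_mismatch_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  ill <- design$illuminants
  ids <- names(ill)
  cam <- design$camera
  table <- chromophore_table(cam$grid)
  seeds <- derive_seeds(design$seed, 4)
  samples <- sample_tissue(design$n_total, seed = seeds[[1]])
  train_samples <- samples[seq_len(design$n_train), ]
  test_samples <- samples[design$n_train + seq_len(design$n_test), ]
  refl_train <- reflectance_spectrum(train_samples, cam$grid, table)
  refl_test <- reflectance_spectrum(test_samples, cam$grid, table)

  render_seeds <- derive_seeds(seeds[[2]], 2 * length(ids))
  train_sets <- test_sets <- setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    train_sets[[i]] <- build_training_set(
      train_samples, ill[[i]], cam, sigma_w = design$sigma_w, table = table,
      reflectance = refl_train, seed = render_seeds[[2 * i - 1]],
      illuminant_id = ids[i])
    test_sets[[i]] <- build_training_set(
      test_samples, ill[[i]], cam, sigma_w = design$sigma_w, table = table,
      reflectance = refl_test, seed = render_seeds[[2 * i]],
      illuminant_id = ids[i])
  }
  fit_seeds <- derive_seeds(seeds[[3]], length(ids))
  regressors <- purrr::map(seq_along(ids), function(i) {
    train_regressor(train_sets[[i]], num_trees = design$num_trees,
                    seed = fit_seeds[[i]])
  })
  names(regressors) <- ids

  res <- purrr::map_dfr(seq_along(ids), function(i) {
    purrr::map_dfr(seq_along(ids), function(j) {
      tibble::tibble(
        test_ls = ids[i],
        condition = if (i == j) "matched" else "mismatched",
        train_ls = ids[j],
        mae_pp = evaluate_oxygenation(regressors[[j]], test_sets[[i]])
      )
    })
  })

  if (!is.null(design$estimates) && nrow(design$estimates) > 0) {
    est <- design$estimates
    est_seeds <- derive_seeds(seeds[[4]], 2 * nrow(est))
    cal <- purrr::map_dfr(seq_len(nrow(est)), function(r) {
      bands <- est$estimate[[r]]
      spec <- if (length(bands) == cam$n_bands) {
        illuminant_from_bands(bands, cam)
      } else bands
      ts <- build_training_set(
        train_samples, spec, cam, sigma_w = design$sigma_w, table = table,
        reflectance = refl_train, seed = est_seeds[[2 * r - 1]],
        illuminant_id = sprintf("%s_hat%d", est$illuminant_id[r], r))
      reg <- train_regressor(ts, num_trees = design$num_trees,
                             seed = est_seeds[[2 * r]])
      tibble::tibble(
        test_ls = est$illuminant_id[r],
        condition = "calibrated",
        train_ls = ts$illuminant_id,
        mae_pp = evaluate_oxygenation(reg, test_sets[[est$illuminant_id[r]]])
      )
    })
    res <- dplyr::bind_rows(res, cal)
  }

  summary <- res |>
    dplyr::group_by(.data$test_ls, .data$condition) |>
    dplyr::summarise(mae_pp = mean(.data$mae_pp), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "mae_pp",
                       names_prefix = "mae_")
  if ("mae_calibrated" %in% names(summary) && "mae_mismatched" %in% names(summary)) {
    summary$reduction_pct <-
      (1 - summary$mae_calibrated / summary$mae_mismatched) * 100
  }
  structure(list(results = res, summary = summary, design = design),
            class = "mismatch_experiment")
}

#' @export
print.mismatch_experiment <- function(x, ...) {
  cat("<mismatch_experiment>\n")
  print(x$summary)
  invisible(x)
}
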