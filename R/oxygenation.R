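#' Build a labeled training/test set under one illuminant
#'
#' Renders each tissue sample's reflectance to camera band measurements under
#' the given illuminant, applies a random per-sample gain and multiplicative
#' band noise, and L1-normalizes each measurement vector (so the gain
#' cancels). Labels are the first-layer oxygenation — the superficial layer
#' dominates reflectance in the layered model. The same samples rendered
#' under different illuminants share identical labels.
#'
#' @param samples A [sample_tissue()] tibble.
#' @param illuminant Spectrum on the camera grid.
#' @param camera A [camera_model()].
#' @param sigma_w Multiplicative band-noise sd (default 0.1).
#' @param gain_range Per-sample gain range (default 0.5-2; cancelled by
#'   normalization, kept for fidelity to the imaging model).
#' @param table A [chromophore_table()] on the camera grid.
#' @param reflectance Optional precomputed reflectance matrix
#'   (`nrow(samples) x n_lambda`) to avoid recomputation across illuminants.
#' @param seed Optional RNG seed (noise and gains).
#' @param illuminant_id Optional label stored with the set.
#' @return A `labeled_spectra` object: list with `X` (rows sum to 1), `y`
#'   (first-layer sox), `illuminant_id`.
#' @export
build_training_set <- function(samples, illuminant, camera, sigma_w = 0.1,
                               gain_range = c(0.5, 2),
                               table = chromophore_table(camera$grid),
                               reflectance = NULL, seed = NULL,
                               illuminant_id = NA_character_) {
  if (nrow(samples) == 0) stop_config("Need at least one tissue sample.")
  if (is.null(reflectance)) {
    reflectance <- reflectance_spectrum(samples, camera$grid, table)
  }
  with_seed(seed, {
    alpha <- runif(nrow(samples), gain_range[1], gain_range[2])
    X <- band_integrate(reflectance, illuminant, camera,
                        alpha = alpha, sigma_w = sigma_w)
    X <- X / rowSums(X)
    structure(
      list(X = X, y = samples$sox_1, illuminant_id = illuminant_id),
      class = "labeled_spectra"
    )
  })
}

#' @export
print.labeled_spectra <- function(x, ...) {
  cat(sprintf("<labeled_spectra> %d samples x %d bands (illuminant %s)\n",
              nrow(x$X), ncol(x$X), x$illuminant_id))
  invisible(x)
}

#' Train the oxygenation ensemble regressor
#'
#' A random-forest ensemble mapping L1-normalized band measurement vectors to
#' oxygenation in `[0, 1]`; deterministic for a fixed seed; predictions
#' clipped to `[0, 1]`.
#'
#' @param train A [build_training_set()] result with at least 100 rows.
#' @param num_trees,min_node_size Forest hyperparameters (defaults 200 / 5).
#' @param seed Optional RNG seed for the forest.
#' @return A `sox_regressor` object.
#' @export
train_regressor <- function(train, num_trees = 200, min_node_size = 5,
                            seed = NULL) {
  stopifnot(inherits(train, "labeled_spectra"))
  if (nrow(train$X) < 100) stop_config("Need at least 100 training rows.")
  df <- as.data.frame(train$X)
  df$.sox <- train$y
  fit <- ranger::ranger(
    dependent.variable.name = ".sox", data = df,
    num.trees = num_trees, min.node.size = min_node_size,
    num.threads = 1,
    seed = if (is.null(seed)) 1L else as.integer(seed)
  )
  structure(
    list(forest = fit, band_ids = colnames(train$X),
         illuminant_id = train$illuminant_id),
    class = "sox_regressor"
  )
}

#' @export
predict.sox_regressor <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "labeled_spectra")) newdata$X else newdata
  df <- as.data.frame(X)
  colnames(df) <- object$band_ids
  p <- predict(object$forest, data = df, num.threads = 1)$predictions
  pmin(pmax(p, 0), 1)
}

#' @export
print.sox_regressor <- function(x, ...) {
  cat(sprintf("<sox_regressor> %d trees, %d bands (illuminant %s)\n",
              x$forest$num.trees, length(x$band_ids), x$illuminant_id))
  invisible(x)
}

#' Illuminant-indexed regressor bank
#'
#' @param ids Unique illuminant identifiers.
#' @param spectra List of stored illuminant spectra (band space or grid
#'   space — any common representation comparable by [angular_error()]).
#' @param regressors List of [train_regressor()] fits, one per id.
#' @return A `regressor_bank` object.
#' @export
regressor_bank <- function(ids, spectra, regressors) {
  if (length(ids) == 0) stop_config("Bank must be non-empty.")
  if (anyDuplicated(ids)) stop_config("Illuminant ids must be unique.")
  if (length(spectra) != length(ids) || length(regressors) != length(ids)) {
    stop_dimension("ids, spectra and regressors must align.")
  }
  structure(list(ids = as.character(ids), spectra = spectra,
                 regressors = regressors),
            class = "regressor_bank")
}

#' Select the bank regressor nearest an illuminant estimate
#'
#' Minimal [angular_error()] between the estimate and each stored spectrum;
#' ties go to the lowest illuminant id (lexicographic).
#'
#' @param bank A [regressor_bank()].
#' @param estimate Illuminant estimate comparable to the stored spectra.
#' @return List with `id`, `spectrum`, `regressor`, `angular_error_deg`.
#' @export
select_regressor <- function(bank, estimate) {
  stopifnot(inherits(bank, "regressor_bank"))
  errs <- vapply(bank$spectra, function(s) angular_error(s, estimate), numeric(1))
  best <- order(errs, bank$ids)[1]
  list(id = bank$ids[best], spectrum = bank$spectra[[best]],
       regressor = bank$regressors[[best]], angular_error_deg = unname(errs[best]))
}

#' Mean absolute oxygenation error
#'
#' @param regressor A [train_regressor()] fit.
#' @param test A [build_training_set()] result used as test set.
#' @return MAE in percentage points: `mean(|yhat - y|) * 100`.
#' @export
evaluate_oxygenation <- function(regressor, test) {
  if (nrow(test$X) == 0) stop_config("Empty test set.")
  mean(abs(predict(regressor, test) - test$y)) * 100
}
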